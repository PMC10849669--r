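# Synthetic catalogs with known ground truth: Dirichlet signature profiles,
# sparse Dirichlet exposure weights, lognormal per-sample burden, and
# Poisson / multinomial / noise-free count sampling.

#' Simulation parameters for synthetic catalogs
#'
#' @param nSamples number of samples.
#' @param nSignatures number of synthetic signatures.
#' @param schema a [ChannelSchema-class]; default [sbs96Schema()].
#' @param signatureConcentration symmetric Dirichlet concentration for the
#'   signature profiles; values < 1 give peaked, COSMIC-like profiles.
#' @param exposuresActivePerSample number of signatures active in each sample
#'   (sparsity); must be in `[1, nSignatures]`.
#' @param burdenMean mean of the per-sample total mutation burden.
#' @param burdenDispersion coefficient of variation of the lognormal burden
#'   distribution (heavy right tail, mimicking the spread of per-cancer-type
#'   mutation counts).
#' @param noise one of `"poisson"` (independent Poisson per channel),
#'   `"multinomial"` (fixed total per sample), `"none"` (rounded expectation).
#' @param seed integer RNG seed. Signature profiles use `seed`; sample i uses
#'   `seed + i`, so adding samples never reshuffles earlier ones.
#' @return a validated list of class `SimulationSpec`.
#' @seealso [generateSignatures()], [generateCatalog()]
#' @export
simulationSpec <- function(nSamples = 50L, nSignatures = 5L,
                           schema = sbs96Schema(),
                           signatureConcentration = 0.1,
                           exposuresActivePerSample = 3L,
                           burdenMean = 5000, burdenDispersion = 1.0,
                           noise = c("poisson", "multinomial", "none"),
                           seed = 20240119L) {
  noise <- match.arg(noise)
  spec <- list(nSamples = as.integer(nSamples),
               nSignatures = as.integer(nSignatures), schema = schema,
               signatureConcentration = signatureConcentration,
               exposuresActivePerSample = as.integer(exposuresActivePerSample),
               burdenMean = burdenMean, burdenDispersion = burdenDispersion,
               noise = noise, seed = as.integer(seed))
  stopifnot(is(schema, "ChannelSchema"),
            spec$nSamples >= 1L, spec$nSignatures >= 1L,
            spec$signatureConcentration > 0,
            spec$exposuresActivePerSample >= 1L,
            spec$exposuresActivePerSample <= spec$nSignatures,
            spec$burdenMean > 0, spec$burdenDispersion > 0)
  class(spec) <- "SimulationSpec"
  spec
}

#' @export
print.SimulationSpec <- function(x, ...) {
  cat(sprintf(paste0("SimulationSpec: %d samples, %d signatures ",
                     "(%d active/sample), burden ~ lognormal(mean %g, CV %g), ",
                     "noise %s, seed %d\n"),
              x$nSamples, x$nSignatures, x$exposuresActivePerSample,
              x$burdenMean, x$burdenDispersion, x$noise, x$seed))
  invisible(x)
}

#' Read a SimulationSpec from a JSON config file
#' @param path JSON file with any subset of the [simulationSpec()] fields
#'   (camelCase); missing fields take the defaults. A `"schema"` field names
#'   the schema (only `"SBS96"` is built in).
#' @return a `SimulationSpec`.
#' @export
readSimulationSpec <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(cfg$schema)) {
    if (!identical(cfg$schema, "SBS96"))
      stop("unknown schema \"", cfg$schema, "\"; built-in schemas: SBS96",
           call. = FALSE)
    cfg$schema <- sbs96Schema()
  }
  known <- names(formals(simulationSpec))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown SimulationSpec field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(simulationSpec, cfg)
}

# Symmetric Dirichlet draw via normalized gammas.
.rdirichlet <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, k)  # guard: all-zero draw at tiny alpha
  g / sum(g)
}

#' Generate synthetic signature profiles
#'
#' Each signature column is an independent draw from a symmetric
#' Dirichlet(`signatureConcentration`) over the schema channels, so columns
#' sum to 1. Reproducible for a fixed seed.
#'
#' @param spec a [simulationSpec()].
#' @return a [SignatureSet-class] with signatures `Sim1..SimK`.
#' @export
generateSignatures <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  k <- length(channelLabels(spec$schema))
  profiles <- vapply(seq_len(spec$nSignatures),
                     function(i) .rdirichlet(k, spec$signatureConcentration),
                     numeric(k))
  colnames(profiles) <- paste0("Sim", seq_len(spec$nSignatures))
  rownames(profiles) <- channelLabels(spec$schema)
  signatureSet(profiles, spec$schema,
               metadata = list(source = "synthetic",
                               concentration = spec$signatureConcentration,
                               seed = spec$seed))
}

#' Generate a synthetic catalog with known ground truth
#'
#' Per sample: `exposuresActivePerSample` signatures are chosen uniformly,
#' their relative weights drawn from Dirichlet(1), the total burden drawn
#' lognormal with mean `burdenMean` and coefficient of variation
#' `burdenDispersion`, and true exposures set to weights x burden. Expected
#' channel counts are profiles times exposures; observed counts are sampled
#' per the noise mode (Poisson per channel; multinomial with n = rounded
#' burden; or the rounded expectation for `"none"`). The ground truth is
#' returned exactly as drawn.
#'
#' @param spec a [simulationSpec()].
#' @return list with `catalog` ([MutationalCatalog-class]), `trueExposures`
#'   (an [ExposureResult-class] whose `rnorm` holds the squared residual of
#'   the observed counts around the noise-free expectation), and `signatures`
#'   ([SignatureSet-class]).
#' @examples
#' sim <- generateCatalog(simulationSpec(nSamples = 3, seed = 42))
#' dim(sim$catalog)
#' @export
generateCatalog <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  sigs <- generateSignatures(spec)
  P <- signatureProfiles(sigs)
  nch <- nrow(P)
  sdlog <- sqrt(log(1 + spec$burdenDispersion^2))
  meanlog <- log(spec$burdenMean) - sdlog^2 / 2
  ids <- sprintf("sample%03d", seq_len(spec$nSamples))
  counts <- matrix(0, spec$nSamples, nch, dimnames = list(ids, rownames(P)))
  expo <- matrix(0, spec$nSamples, ncol(P),
                 dimnames = list(ids, colnames(P)))
  rn <- numeric(spec$nSamples)
  for (i in seq_len(spec$nSamples)) {
    set.seed(spec$seed + i)   # per-sample sub-stream
    active <- sample.int(spec$nSignatures, spec$exposuresActivePerSample)
    w <- .rdirichlet(spec$exposuresActivePerSample, 1)
    burden <- stats::rlnorm(1, meanlog, sdlog)
    expo[i, active] <- w * burden
    lambda <- drop(P %*% expo[i, ])
    counts[i, ] <- switch(spec$noise,
      poisson = stats::rpois(nch, lambda),
      multinomial = drop(stats::rmultinom(1, round(burden),
                                          prob = lambda / sum(lambda))),
      none = round(lambda))
    rn[i] <- sum((counts[i, ] - lambda)^2)
  }
  list(catalog = mutationalCatalog(counts, spec$schema),
       trueExposures = exposureResult(expo, rn),
       signatures = sigs)
}
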
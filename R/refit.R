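#' Reference signature set
#'
#' Channels x signatures matrix of per-channel probabilities; every signature
#' column sums to 1 (COSMIC-style).
#'
#' @slot schema the [ChannelSchema-class] describing the rows.
#' @slot profiles numeric matrix, channels x signatures; rownames are channel
#'   labels in schema order, colnames are signature ids.
#' @slot metadata named list (reference set name, genome build, ...).
#' @export
setClass("SignatureSet",
  representation(schema = "ChannelSchema", profiles = "matrix",
                 metadata = "list"),
  validity = function(object) {
    p <- object@profiles
    if (!is.numeric(p)) return("profiles must be numeric")
    if (nrow(p) != length(object@schema@channels))
      return("profiles row count must equal schema channel count")
    if (!identical(rownames(p), object@schema@channels))
      return("profiles rownames must equal schema channels in order")
    if (is.null(colnames(p)) || anyDuplicated(colnames(p)))
      return("signature ids must be unique colnames")
    if (any(!is.finite(p)) || any(p < 0))
      return("profiles must be finite and non-negative")
    s <- colSums(p)
    if (any(abs(s - 1) > 1e-6))
      return(paste0("signature column(s) do not sum to 1: ",
                    paste(colnames(p)[abs(s - 1) > 1e-6], collapse = ", ")))
    TRUE
  }
)

#' Construct a SignatureSet
#' @param profiles channels x signatures matrix; columns are probability
#'   vectors. Rows are matched to `schema` by rowname when present.
#' @param schema a [ChannelSchema-class]; default [sbs96Schema()].
#' @param metadata optional named list.
#' @return a [SignatureSet-class].
#' @export
signatureSet <- function(profiles, schema = sbs96Schema(), metadata = list()) {
  profiles <- as.matrix(profiles)
  if (!is.null(rownames(profiles))) {
    if (!setequal(rownames(profiles), schema@channels))
      stop("profile rownames do not match schema \"", schema@name, "\" channels",
           call. = FALSE)
    profiles <- profiles[schema@channels, , drop = FALSE]
  } else {
    rownames(profiles) <- schema@channels
  }
  if (is.null(colnames(profiles)))
    colnames(profiles) <- paste0("S", seq_len(ncol(profiles)))
  new("SignatureSet", schema = schema, profiles = profiles,
      metadata = metadata)
}

#' @describeIn SignatureSet signature ids.
#' @param object a `SignatureSet`.
#' @export
setGeneric("signatureIds", function(object) standardGeneric("signatureIds"))

#' @rdname SignatureSet-class
#' @export
setMethod("signatureIds", "SignatureSet", function(object)
  colnames(object@profiles))

#' @describeIn SignatureSet the channels x signatures probability matrix.
#' @export
setGeneric("signatureProfiles",
           function(object) standardGeneric("signatureProfiles"))

#' @rdname SignatureSet-class
#' @export
setMethod("signatureProfiles", "SignatureSet", function(object)
  object@profiles)

#' @rdname SignatureSet-class
#' @export
setMethod("channelSchema", "SignatureSet", function(object) object@schema)

setMethod("show", "SignatureSet", function(object) {
  cat(sprintf("SignatureSet: %d signatures over %d channels (%s)\n",
              ncol(object@profiles), nrow(object@profiles),
              object@schema@name))
  cat("  ", paste(utils::head(colnames(object@profiles), 8L),
                  collapse = ", "),
      if (ncol(object@profiles) > 8L) ", ..." else "", "\n", sep = "")
})

#' Signature exposures with residual diagnostics
#'
#' Non-negative activity of each reference signature in each sample
#' (mutation-count units) together with the per-sample r-norm: the sum of
#' squared residuals of the NNLS reconstruction.
#'
#' @slot exposures numeric matrix, samples x signatures, non-negative;
#'   rownames sample ids, colnames signature ids.
#' @slot rnorm named non-negative numeric, one value per sample.
#' @export
setClass("ExposureResult",
  representation(exposures = "matrix", rnorm = "numeric"),
  validity = function(object) {
    e <- object@exposures
    if (is.null(rownames(e)) || is.null(colnames(e)))
      return("exposures must have sample rownames and signature colnames")
    if (anyDuplicated(rownames(e)) || anyDuplicated(colnames(e)))
      return("sample and signature ids must be unique")
    if (any(!is.finite(e)) || any(e < 0))
      return("exposures must be finite and non-negative")
    if (length(object@rnorm) != nrow(e))
      return("rnorm must have one value per sample")
    if (any(!is.finite(object@rnorm)) || any(object@rnorm < 0))
      return("rnorm must be finite and non-negative")
    TRUE
  }
)

#' Construct an ExposureResult
#' @param exposures samples x signatures non-negative matrix.
#' @param rnorm per-sample sum of squared residuals.
#' @return an [ExposureResult-class].
#' @export
exposureResult <- function(exposures, rnorm) {
  exposures <- as.matrix(exposures)
  rnorm <- stats::setNames(as.numeric(rnorm), rownames(exposures))
  new("ExposureResult", exposures = exposures, rnorm = rnorm)
}

#' @describeIn ExposureResult the samples x signatures activity matrix.
#' @param object an `ExposureResult`.
#' @export
setGeneric("exposureMatrix",
           function(object) standardGeneric("exposureMatrix"))

#' @rdname ExposureResult-class
#' @export
setMethod("exposureMatrix", "ExposureResult", function(object)
  object@exposures)

#' @describeIn ExposureResult per-sample r-norm (sum of squared residuals).
#' @export
setGeneric("rnormValues", function(object) standardGeneric("rnormValues"))

#' @rdname ExposureResult-class
#' @export
setMethod("rnormValues", "ExposureResult", function(object) object@rnorm)

#' @rdname ExposureResult-class
#' @export
setMethod("sampleIds", "ExposureResult", function(object)
  rownames(object@exposures))

#' @rdname ExposureResult-class
#' @export
setMethod("signatureIds", "ExposureResult", function(object)
  colnames(object@exposures))

setMethod("show", "ExposureResult", function(object) {
  cat(sprintf("ExposureResult: %d samples x %d signatures\n",
              nrow(object@exposures), ncol(object@exposures)))
  cat(sprintf("  r-norm: median %.4g, max %.4g\n",
              stats::median(object@rnorm), max(object@rnorm)))
})

#' Non-negative least squares by the Lawson-Hanson active-set method
#'
#' Minimizes \eqn{\|Ax - b\|^2} subject to \eqn{x \ge 0}. The active set is
#' grown by the largest positive dual (gradient) component, lowest index on
#' exact ties; the dual-feasibility test uses a tolerance of
#' `10 * .Machine$double.eps * max(|A' b|)` so the result is scale-aware. At
#' the solution the Karush-Kuhn-Tucker conditions hold: the gradient is ~0 on
#' positive coefficients and non-positive (within tolerance) on the rest.
#'
#' @param design numeric matrix A, channels x k, with no all-zero column.
#' @param target numeric vector b of length `nrow(design)`.
#' @param maxIter iteration cap; default `3 * ncol(design)` outer iterations.
#'   Exceeding it raises a numerical-failure error rather than returning a
#'   non-optimal point.
#' @return list with `coefficients` (non-negative, length k) and `rnorm`
#'   (the minimum sum of squared residuals).
#' @examples
#' A <- diag(3)
#' nnlsSolve(A, c(1, 0, 2))$coefficients
#' @export
nnlsSolve <- function(design, target, maxIter = 3L * ncol(design)) {
  design <- as.matrix(design)
  target <- as.numeric(target)
  if (any(!is.finite(design)) || any(!is.finite(target)))
    stop("non-finite values in design or target", call. = FALSE)
  if (ncol(design) < 1L)
    stop("design must have at least one column", call. = FALSE)
  if (nrow(design) != length(target))
    stop("dimension mismatch: design has ", nrow(design),
         " rows but target has length ", length(target), call. = FALSE)
  if (any(colSums(design != 0) == 0L))
    stop("design contains an all-zero column", call. = FALSE)

  k <- ncol(design)
  x <- numeric(k)
  passive <- logical(k)           # TRUE = in the positive (passive) set
  w <- drop(crossprod(design, target))  # gradient at x = 0
  tol <- 10 * .Machine$double.eps * max(abs(w), 1)
  iter <- 0L

  repeat {
    free <- which(!passive)
    if (length(free) == 0L || max(w[free]) <= tol) break
    iter <- iter + 1L
    if (iter > maxIter)
      stop("NNLS failed to converge within ", maxIter, " iterations",
           call. = FALSE)
    # enter the variable with the largest dual; which.max takes lowest index
    # on exact ties
    j <- free[which.max(w[free])]
    passive[j] <- TRUE

    repeat {
      P <- which(passive)
      z <- numeric(k)
      qrP <- qr(design[, P, drop = FALSE])
      zP <- qr.coef(qrP, target)
      zP[is.na(zP)] <- 0          # rank-deficient passive set: drop dependents
      z[P] <- zP
      if (all(z[P] > 0)) break
      # inner step: move toward z until a passive coefficient hits zero
      drop <- P[z[P] <= 0]
      alpha <- min(x[drop] / (x[drop] - z[drop]))
      x <- x + alpha * (z - x)
      passive[P][x[P] <= tol & z[P] <= 0] <- FALSE
      x[!passive] <- 0
    }
    x <- z
    w <- drop(crossprod(design, target - design %*% x))
  }
  resid <- target - drop(design %*% x)
  list(coefficients = x, rnorm = sum(resid^2))
}

#' Refit signature exposures for every sample of a catalog
#'
#' Solves one NNLS problem per sample: exposures for sample i minimize
#' \eqn{\|P e - c_i\|^2, e \ge 0}, where P is the signature profile matrix and
#' \eqn{c_i} the sample's channel counts. The r-norm reported per sample is
#' that minimum: the sum of squared residuals of the decomposition. The fit is
#' deterministic.
#'
#' By default the fit is on raw counts, so exposures are in mutation-count
#' units and the r-norm is on the count scale; `normalizeInput = TRUE` fits
#' the normalized spectrum instead (exposures then sum to ~1 per sample).
#'
#' @param catalog a [MutationalCatalog-class].
#' @param signatures a [SignatureSet-class] on the same schema (same labels,
#'   same order).
#' @param normalizeInput fit normalized spectra instead of raw counts.
#' @return an [ExposureResult-class].
#' @examples
#' sim <- generateCatalog(simulationSpec(nSamples = 4, seed = 7))
#' res <- refitExposures(sim$catalog, sim$signatures)
#' rnormValues(res)
#' @export
refitExposures <- function(catalog, signatures, normalizeInput = FALSE) {
  stopifnot(is(catalog, "MutationalCatalog"), is(signatures, "SignatureSet"))
  a <- channelLabels(channelSchema(catalog))
  b <- channelLabels(channelSchema(signatures))
  if (!identical(a, b)) {
    diff <- which(a[seq_len(min(length(a), length(b)))] !=
                    b[seq_len(min(length(a), length(b)))])
    first <- if (length(diff)) a[diff[1L]] else
      c(a, b)[length(c(a, b))]
    stop("catalog and signature schemas differ; first differing channel: ",
         first, call. = FALSE)
  }
  P <- signatureProfiles(signatures)
  cts <- countMatrix(catalog)
  n <- nrow(cts)
  expo <- matrix(0, n, ncol(P),
                 dimnames = list(rownames(cts), colnames(P)))
  rn <- numeric(n)
  for (i in seq_len(n)) {
    y <- cts[i, ]
    if (normalizeInput && sum(y) > 0) y <- y / sum(y)
    fit <- nnlsSolve(P, y)
    expo[i, ] <- fit$coefficients
    rn[i] <- fit$rnorm
  }
  exposureResult(expo, rn)
}

#' Relative exposures of one sample
#'
#' Activities of each signature in the sample together with their fractions of
#' the sample's total activity (the pie-chart view of a decomposition). Rows
#' are sorted by fraction descending, ties broken by signature id. If every
#' activity is zero, all fractions are zero and a warning is issued.
#'
#' @param result an [ExposureResult-class].
#' @param sampleId sample to extract.
#' @return data.frame with columns `signature`, `activity`, `fraction`.
#' @export
relativeExposures <- function(result, sampleId) {
  stopifnot(is(result, "ExposureResult"))
  ids <- rownames(result@exposures)
  if (!sampleId %in% ids)
    stop("unknown sample \"", sampleId, "\"; available: ",
         paste(utils::head(ids, 10L), collapse = ", "),
         if (length(ids) > 10L) ", ..." else "", call. = FALSE)
  act <- result@exposures[sampleId, ]
  tot <- sum(act)
  frac <- if (tot > 0) act / tot else {
    warning("sample \"", sampleId, "\" has no positive activity; ",
            "all fractions set to 0", call. = FALSE)
    act * 0
  }
  out <- data.frame(signature = names(act), activity = unname(act),
                    fraction = unname(frac), stringsAsFactors = FALSE)
  out <- out[order(-out$fraction, out$signature), ]
  rownames(out) <- NULL
  out
}
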
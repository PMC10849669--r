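#' Mutational catalog: samples by channels count matrix
#'
#' Container for observed mutation counts. Rows are samples, columns are the
#' channels of a [ChannelSchema-class]; entries are non-negative integers.
#' Optional per-sample metadata (cancer type, study, ...) lives in a
#' data.frame keyed by sample id.
#'
#' @slot schema the [ChannelSchema-class] describing the columns.
#' @slot counts numeric matrix, samples x channels, non-negative integers;
#'   rownames are sample ids, colnames are channel labels in schema order.
#' @slot sampleData data.frame of per-sample metadata, one row per sample.
#'
#' @seealso [mutationalCatalog()], [readCatalogCsv()], [sampleSummary()]
#' @export
setClass("MutationalCatalog",
  representation(schema = "ChannelSchema", counts = "matrix",
                 sampleData = "data.frame"),
  validity = function(object) {
    cts <- object@counts
    sch <- object@schema
    if (!is.numeric(cts)) return("counts must be numeric")
    if (ncol(cts) != length(sch@channels))
      return(sprintf("counts has %d columns but schema \"%s\" has %d channels",
                     ncol(cts), sch@name, length(sch@channels)))
    if (!identical(colnames(cts), sch@channels))
      return("counts colnames must equal schema channels in order")
    ids <- rownames(cts)
    if (is.null(ids) || any(!nzchar(ids)))
      return("counts must have non-empty sample ids as rownames")
    if (anyDuplicated(ids))
      return(paste0("duplicate sample id(s): ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (any(!is.finite(cts)) || any(cts < 0))
      return("counts must be finite and non-negative")
    if (any(cts != round(cts)))
      return("counts must be integral")
    if (nrow(object@sampleData) != nrow(cts))
      return("sampleData must have one row per sample")
    if (!identical(rownames(object@sampleData), ids))
      return("sampleData rownames must equal sample ids")
    TRUE
  }
)

#' Construct a MutationalCatalog
#'
#' @param counts samples x channels matrix of non-negative integer counts.
#'   Columns are matched to `schema` by name when colnames are present and
#'   reordered into schema order; otherwise they are taken to already be in
#'   schema order.
#' @param schema a [ChannelSchema-class]; default [sbs96Schema()].
#' @param sampleData optional data.frame of per-sample metadata with rownames
#'   equal to (a superset of) the sample ids.
#' @return a [MutationalCatalog-class].
#' @examples
#' sch <- sbs96Schema()
#' m <- matrix(0L, 2, 96, dimnames = list(c("s1", "s2"), channelLabels(sch)))
#' m[1, "A[C>T]G"] <- 5L
#' mutationalCatalog(m)
#' @export
mutationalCatalog <- function(counts, schema = sbs96Schema(),
                              sampleData = NULL) {
  counts <- as.matrix(counts)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample id(s): ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  if (!is.null(colnames(counts))) {
    unknown <- setdiff(colnames(counts), schema@channels)
    if (length(unknown))
      stop("channel label(s) not in schema \"", schema@name, "\": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    full <- matrix(0, nrow(counts), length(schema@channels),
                   dimnames = list(rownames(counts), schema@channels))
    full[, colnames(counts)] <- counts
    counts <- full
  } else {
    colnames(counts) <- schema@channels
  }
  storage.mode(counts) <- "double"
  if (is.null(sampleData)) {
    sampleData <- data.frame(row.names = rownames(counts))
  } else {
    missing <- setdiff(rownames(counts), rownames(sampleData))
    if (length(missing))
      stop("sampleData lacks rows for sample(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    sampleData <- sampleData[rownames(counts), , drop = FALSE]
  }
  new("MutationalCatalog", schema = schema, counts = counts,
      sampleData = sampleData)
}

#' @describeIn MutationalCatalog sample ids in catalog order.
#' @param object,x a `MutationalCatalog`.
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname MutationalCatalog-class
#' @export
setMethod("sampleIds", "MutationalCatalog", function(object)
  rownames(object@counts))

#' @describeIn MutationalCatalog the counts matrix (samples x channels).
#' @export
setGeneric("countMatrix", function(object) standardGeneric("countMatrix"))

#' @rdname MutationalCatalog-class
#' @export
setMethod("countMatrix", "MutationalCatalog", function(object) object@counts)

#' @describeIn MutationalCatalog per-sample metadata data.frame.
#' @export
setGeneric("sampleData", function(object) standardGeneric("sampleData"))

#' @rdname MutationalCatalog-class
#' @export
setMethod("sampleData", "MutationalCatalog", function(object)
  object@sampleData)

#' @describeIn MutationalCatalog the channel schema.
#' @export
setGeneric("channelSchema", function(object) standardGeneric("channelSchema"))

#' @rdname MutationalCatalog-class
#' @export
setMethod("channelSchema", "MutationalCatalog", function(object)
  object@schema)

#' @rdname MutationalCatalog-class
#' @export
setMethod("dim", "MutationalCatalog", function(x) dim(x@counts))

setMethod("show", "MutationalCatalog", function(object) {
  cat(sprintf("MutationalCatalog: %d samples x %d channels (%s), %s mutations\n",
              nrow(object@counts), ncol(object@counts), object@schema@name,
              format(sum(object@counts), big.mark = ",")))
  if (ncol(object@sampleData))
    cat("  sample metadata:", paste(colnames(object@sampleData),
                                    collapse = ", "), "\n")
})

.checkSample <- function(catalog, sampleId) {
  ids <- sampleIds(catalog)
  if (!sampleId %in% ids)
    stop("unknown sample \"", sampleId, "\"; available: ",
         paste(utils::head(ids, 10L), collapse = ", "),
         if (length(ids) > 10L) ", ..." else "", call. = FALSE)
}

#' Normalized mutation spectrum of one sample
#'
#' Divides a sample's channel counts by its total. A zero-count sample yields
#' the all-zero spectrum (no division error), the empty-sample sentinel.
#'
#' @param catalog a [MutationalCatalog-class].
#' @param sampleId sample to extract.
#' @return named numeric vector over channels; sums to 1 unless all zero.
#' @export
toSpectrum <- function(catalog, sampleId) {
  stopifnot(is(catalog, "MutationalCatalog"))
  .checkSample(catalog, sampleId)
  row <- catalog@counts[sampleId, ]
  tot <- sum(row)
  if (tot == 0) row else row / tot
}

#' Per-sample mutation totals and substitution-class subtotals
#'
#' One row per sample in catalog order with the total mutation count and a
#' subtotal per central substitution class (for SBS96: C>A, C>G, C>T, T>A,
#' T>C, T>G). Subtotals always sum to the total.
#'
#' @param catalog a [MutationalCatalog-class].
#' @return data.frame with columns `sample`, `total`, then one column per
#'   substitution class.
#' @export
sampleSummary <- function(catalog) {
  stopifnot(is(catalog, "MutationalCatalog"))
  classes <- substitutionOf(catalog@schema)
  classLevels <- unique(classes)
  sub <- sapply(classLevels, function(cl)
    rowSums(catalog@counts[, classes == cl, drop = FALSE]))
  if (nrow(catalog@counts) == 1L) sub <- matrix(sub, nrow = 1L,
                                                dimnames = list(NULL, classLevels))
  out <- data.frame(sample = sampleIds(catalog),
                    total = rowSums(catalog@counts),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(sub, check.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Compare the mutation spectra of two samples
#'
#' Builds the per-channel comparison table behind a two-sample spectra plot:
#' both normalized spectra, their difference (a - b), plus the cosine
#' similarity of the two spectra and the residual sum of squares
#' (sum of squared per-channel differences).
#'
#' @param catalog a [MutationalCatalog-class].
#' @param sampleA,sampleB sample ids to compare.
#' @return list with elements `table` (data.frame: `channel`, `valueA`,
#'   `valueB`, `difference`), `cosineSimilarity`, and `rss`.
#' @examples
#' sim <- generateCatalog(simulationSpec(nSamples = 3, seed = 1))
#' cmp <- compareSpectra(sim$catalog, sampleIds(sim$catalog)[1],
#'                       sampleIds(sim$catalog)[2])
#' cmp$cosineSimilarity
#' @export
compareSpectra <- function(catalog, sampleA, sampleB) {
  stopifnot(is(catalog, "MutationalCatalog"))
  .checkSample(catalog, sampleA)
  .checkSample(catalog, sampleB)
  a <- toSpectrum(catalog, sampleA)
  b <- toSpectrum(catalog, sampleB)
  tab <- data.frame(channel = channelLabels(catalog@schema),
                    valueA = unname(a), valueB = unname(b),
                    difference = unname(a - b), stringsAsFactors = FALSE)
  list(table = tab,
       cosineSimilarity = cosineSimilarity(a, b),
       rss = sum((a - b)^2))
}

#' Grouped boxplot statistics of log10 mutation totals
#'
#' For each level of a per-sample metadata key, computes boxplot statistics of
#' the log10-transformed total mutation counts: quartiles by linear
#' interpolation, Tukey whiskers at the most extreme observation within
#' 1.5 x IQR of the quartiles (never retracting past the box edges, so
#' `whiskerLow <= q1 <= q3 <= whiskerHigh` always holds), and outliers
#' beyond the fences. Samples with
#' zero total are excluded with a warning (log of zero is undefined).
#'
#' @param catalog a [MutationalCatalog-class].
#' @param groupKey name of a column of `sampleData(catalog)`.
#' @return data.frame with one row per group: `group`, `n`, `median`, `q1`,
#'   `q3`, `whiskerLow`, `whiskerHigh`, and a list-column `outliers`.
#' @export
groupedLogBoxplot <- function(catalog, groupKey) {
  stopifnot(is(catalog, "MutationalCatalog"))
  sd <- sampleData(catalog)
  if (!groupKey %in% colnames(sd))
    stop("metadata key \"", groupKey, "\" missing for sample(s): ",
         paste(sampleIds(catalog), collapse = ", "), call. = FALSE)
  groups <- as.character(sd[[groupKey]])
  if (anyNA(groups) || any(!nzchar(groups)))
    stop("metadata key \"", groupKey, "\" missing for sample(s): ",
         paste(sampleIds(catalog)[is.na(groups) | !nzchar(groups)],
               collapse = ", "), call. = FALSE)
  totals <- rowSums(catalog@counts)
  zero <- totals == 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " zero-total sample(s) from log boxplot: ",
            paste(sampleIds(catalog)[zero], collapse = ", "), call. = FALSE)
    totals <- totals[!zero]
    groups <- groups[!zero]
  }
  res <- lapply(unique(groups), function(g) {
    x <- log10(totals[groups == g])
    q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    inFence <- x >= q[1] - 1.5 * iqr & x <= q[3] + 1.5 * iqr
    wl <- min(x[inFence], q[1])   # clamp: a whisker never retracts past the box
    wh <- max(x[inFence], q[3])
    data.frame(group = g, n = length(x), median = q[2], q1 = q[1], q3 = q[3],
               whiskerLow = wl, whiskerHigh = wh,
               outliers = I(list(unname(sort(x[!inFence])))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
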
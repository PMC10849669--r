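# File formats:
#   wide catalog CSV:  sample,<label1>,...,<labelN>   (one row per sample)
#   long catalog CSV:  sample,mutationType,mutations
#   portal JSON:       array of {sample, profile, matrix, mutationType, mutations}
#   signature CSV:     mutationType,<sig1>,...,<sigK>  (rows in schema order)
#   exposure CSV:      sample,<sig1>,...,<sigK>,rnorm

.validateCounts <- function(counts, where) {
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad))
    stop("negative or non-integer count at ", where, " row ",
         bad[1L], call. = FALSE)
}

#' Read a mutational catalog from CSV
#'
#' Auto-detects the layout: wide (header `sample,<channel labels...>`) or long
#' (header `sample,mutationType,mutations`). In either layout, channels are
#' reordered into schema order and channels absent from a long file are filled
#' with zero. Unknown channel labels, duplicate sample ids and negative or
#' non-integer counts are rejected.
#'
#' @param path CSV file path.
#' @param schema a [ChannelSchema-class]; default [sbs96Schema()].
#' @return a [MutationalCatalog-class].
#' @seealso [writeCatalogCsv()], [parsePortalJson()]
#' @export
readCatalogCsv <- function(path, schema = sbs96Schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample" %in% colnames(df))
    stop("catalog CSV must have a \"sample\" column: ", path, call. = FALSE)
  if (all(c("mutationType", "mutations") %in% colnames(df))) {
    return(.catalogFromLong(df$sample, df$mutationType, df$mutations, schema,
                            where = path))
  }
  labels <- setdiff(colnames(df), "sample")
  unknown <- setdiff(labels, channelLabels(schema))
  if (length(unknown))
    stop("channel label(s) not in schema \"", schema@name, "\": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  ids <- as.character(df$sample)
  if (anyDuplicated(ids))
    stop("duplicate sample id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  counts <- as.matrix(df[, labels, drop = FALSE])
  if (!is.numeric(counts))
    stop("non-numeric count in ", path, call. = FALSE)
  .validateCounts(counts, path)
  rownames(counts) <- ids
  mutationalCatalog(counts, schema)
}

.catalogFromLong <- function(sample, mutationType, mutations, schema, where) {
  unknown <- setdiff(unique(mutationType), channelLabels(schema))
  if (length(unknown))
    stop("channel label(s) not in schema \"", schema@name, "\": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  mutations <- as.numeric(mutations)
  .validateCounts(mutations, where)
  ids <- unique(as.character(sample))
  counts <- matrix(0, length(ids), length(channelLabels(schema)),
                   dimnames = list(ids, channelLabels(schema)))
  for (i in seq_along(sample))
    counts[as.character(sample[i]), mutationType[i]] <-
      counts[as.character(sample[i]), mutationType[i]] + mutations[i]
  mutationalCatalog(counts, schema)
}

#' Write a mutational catalog as wide CSV
#'
#' First column `sample`, then one column per channel in schema order.
#' Re-reading with [readCatalogCsv()] reproduces the catalog exactly.
#'
#' @param catalog a [MutationalCatalog-class].
#' @param path output file path.
#' @export
writeCatalogCsv <- function(catalog, path) {
  stopifnot(is(catalog, "MutationalCatalog"))
  df <- data.frame(sample = sampleIds(catalog), check.names = FALSE,
                   stringsAsFactors = FALSE)
  cts <- countMatrix(catalog)
  storage.mode(cts) <- "integer"
  df <- cbind(df, as.data.frame(cts, check.names = FALSE))
  .writeCsv(df, path)
}

.writeCsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write ", path, ": ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Parse a portal-dialect JSON payload into a catalog
#'
#' The payload emulates the record shape of mutational-signature portal API
#' responses (this dialect is an emulation; the portal's exact field names are
#' not published): an array of objects with fields `sample`, `profile` (schema
#' family, e.g. `"SBS"`), `matrix` (channel count, e.g. `96`), `mutationType`
#' (channel label) and `mutations` (count). Records whose profile or matrix
#' disagree with the requested schema are rejected. Channels not mentioned are
#' filled with zero; the result is identical to reading the equivalent long
#' CSV.
#'
#' @param payload JSON text (or path to a `.json` file).
#' @param schema a [ChannelSchema-class]; default [sbs96Schema()].
#' @return a [MutationalCatalog-class].
#' @export
parsePortalJson <- function(payload, schema = sbs96Schema()) {
  recs <- jsonlite::fromJSON(payload, simplifyVector = FALSE)
  if (!is.list(recs))
    stop("portal payload must be a JSON array of records", call. = FALSE)
  if (length(recs) == 0L)
    stop("no records in portal payload", call. = FALSE)
  wantProfile <- gsub("[0-9]+$", "", schema@name)
  wantMatrix <- length(schema@channels)
  need <- c("sample", "profile", "matrix", "mutationType", "mutations")
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    miss <- setdiff(need, names(r))
    if (length(miss))
      stop("record ", i, " missing field(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (!identical(as.character(r$profile), wantProfile) ||
        as.numeric(r$matrix) != wantMatrix)
      stop("record ", i, " profile/matrix (", r$profile, "/", r$matrix,
           ") does not match schema \"", schema@name, "\"", call. = FALSE)
  }
  .catalogFromLong(vapply(recs, function(r) as.character(r$sample), ""),
                   vapply(recs, function(r) as.character(r$mutationType), ""),
                   vapply(recs, function(r) as.numeric(r$mutations), 0),
                   schema, where = "portal payload")
}

#' Read a reference signature set from CSV
#'
#' Header `mutationType,<sig1>,...,<sigK>`; one row per channel. Rows are
#' reordered into schema order; every channel must be present and every
#' signature column must be a probability vector (sums to 1).
#'
#' @param path CSV file path.
#' @param schema a [ChannelSchema-class]; default [sbs96Schema()].
#' @return a [SignatureSet-class].
#' @export
readSignatureCsv <- function(path, schema = sbs96Schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"mutationType" %in% colnames(df))
    stop("signature CSV must have a \"mutationType\" column: ", path,
         call. = FALSE)
  labels <- channelLabels(schema)
  unknown <- setdiff(df$mutationType, labels)
  if (length(unknown))
    stop("channel label(s) not in schema \"", schema@name, "\": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(labels, df$mutationType)
  if (length(missing))
    stop("signature CSV missing channel(s): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  profiles <- as.matrix(df[match(labels, df$mutationType),
                           setdiff(colnames(df), "mutationType"),
                           drop = FALSE])
  rownames(profiles) <- labels
  signatureSet(profiles, schema)
}

#' Write a signature set as CSV
#' @param signatures a [SignatureSet-class].
#' @param path output file path.
#' @export
writeSignatureCsv <- function(signatures, path) {
  stopifnot(is(signatures, "SignatureSet"))
  df <- data.frame(mutationType = channelLabels(signatures@schema),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(signatures@profiles, check.names = FALSE))
  .writeCsv(df, path)
}

#' Write exposures as CSV
#'
#' Header `sample,<sig1>,...,<sigK>,rnorm`.
#' @param result an [ExposureResult-class].
#' @param path output file path.
#' @export
writeExposureCsv <- function(result, path) {
  stopifnot(is(result, "ExposureResult"))
  df <- data.frame(sample = rownames(result@exposures), check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(result@exposures, check.names = FALSE))
  df$rnorm <- unname(result@rnorm)
  .writeCsv(df, path)
}

#' Read exposures from CSV
#' @param path CSV written by [writeExposureCsv()].
#' @return an [ExposureResult-class].
#' @export
readExposureCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample", "rnorm") %in% colnames(df)))
    stop("exposure CSV must have \"sample\" and \"rnorm\" columns: ", path,
         call. = FALSE)
  sigs <- setdiff(colnames(df), c("sample", "rnorm"))
  exposures <- as.matrix(df[, sigs, drop = FALSE])
  rownames(exposures) <- df$sample
  exposureResult(exposures, df$rnorm)
}

#' Write a distance matrix as square CSV with id header row and column
#' @param dist a [DistanceMatrix-class].
#' @param path output file path.
#' @export
writeDistanceCsv <- function(dist, path) {
  stopifnot(is(dist, "DistanceMatrix"))
  df <- data.frame(id = dist@ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(dist@values, check.names = FALSE))
  .writeCsv(df, path)
}

#' Write any derived table (summary, comparison, boxplot stats) as CSV
#'
#' Shared writer for the plot-ready tables the package produces. List-columns
#' (e.g. boxplot outliers) are flattened to semicolon-separated strings.
#'
#' @param table a data.frame.
#' @param path output file path.
#' @export
writeTableCsv <- function(table, path) {
  isList <- vapply(table, is.list, TRUE)
  for (j in which(isList))
    table[[j]] <- vapply(table[[j]], function(v)
      paste(format(v, trim = TRUE), collapse = ";"), "")
  .writeCsv(table, path)
}
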
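#' Symmetric pairwise cosine-distance matrix
#'
#' Cosine distance is 1 minus cosine similarity: 0 for identical directions,
#' 1 for disjoint support. For non-negative input vectors all entries lie in
#' `[0, 1]`; the diagonal is zero.
#'
#' @slot ids ordered unique labels of the rows/columns.
#' @slot values n x n numeric matrix of cosine distances.
#' @export
setClass("DistanceMatrix",
  representation(ids = "character", values = "matrix"),
  validity = function(object) {
    v <- object@values
    n <- length(object@ids)
    if (anyDuplicated(object@ids)) return("ids must be unique")
    if (nrow(v) != n || ncol(v) != n)
      return("values must be a square matrix matching ids")
    if (any(!is.finite(v))) return("distance values must be finite")
    if (max(abs(v - t(v))) > 1e-12) return("matrix must be symmetric")
    if (any(abs(diag(v)) > 0)) return("diagonal must be zero")
    TRUE
  }
)

#' @rdname DistanceMatrix-class
#' @param x,object a `DistanceMatrix`.
#' @export
setMethod("dim", "DistanceMatrix", function(x) dim(x@values))

#' Distance values as a plain matrix
#' @param dist a [DistanceMatrix-class].
#' @return numeric matrix with ids as dimnames.
#' @export
distanceValues <- function(dist) {
  stopifnot(is(dist, "DistanceMatrix"))
  v <- dist@values
  dimnames(v) <- list(dist@ids, dist@ids)
  v
}

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix: %d x %d (cosine distance)\n",
              length(object@ids), length(object@ids)))
})

#' Cosine similarity of two non-negative vectors
#'
#' \eqn{u \cdot v / (\|u\| \|v\|)}; lies in `[0, 1]` for non-negative inputs.
#' If either vector is all-zero the similarity is defined as 0 (maximally
#' distant) and a warning is issued — erroring would break batch runs over
#' catalogs containing empty samples.
#'
#' @param u,v numeric vectors of equal length.
#' @return a number in `[0, 1]`.
#' @export
cosineSimilarity <- function(u, v) {
  if (length(u) != length(v))
    stop("length mismatch: ", length(u), " vs ", length(v), call. = FALSE)
  if (any(!is.finite(u)) || any(!is.finite(v)))
    stop("non-finite values in input vectors", call. = FALSE)
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    warning("zero vector in cosine similarity; returning 0", call. = FALSE)
    return(0)
  }
  sum(u * v) / (nu * nv)
}

#' Pairwise cosine distances between labelled row vectors
#'
#' Entry (i, j) is `1 - cosineSimilarity(row_i, row_j)`. Cosine is invariant
#' to positive scaling, so counts and normalized spectra give the same matrix.
#'
#' @param rows numeric matrix with >= 2 rows; rownames are used as ids
#'   (defaults to `V1..Vn`).
#' @return a [DistanceMatrix-class].
#' @examples
#' m <- rbind(a = c(1, 0), b = c(0, 1), c = c(2, 0))
#' distanceValues(pairwiseCosineDistance(m))
#' @export
pairwiseCosineDistance <- function(rows) {
  rows <- as.matrix(rows)
  if (nrow(rows) < 2L)
    stop("need at least 2 rows to build a distance matrix", call. = FALSE)
  ids <- rownames(rows)
  if (is.null(ids)) ids <- paste0("V", seq_len(nrow(rows)))
  norms <- sqrt(rowSums(rows^2))
  if (any(norms == 0))
    warning("zero vector(s) in distance computation: ",
            paste(ids[norms == 0], collapse = ", "),
            "; treated as maximally distant", call. = FALSE)
  safe <- ifelse(norms == 0, 1, norms)
  sim <- tcrossprod(rows / safe)
  sim[norms == 0, ] <- 0
  sim[, norms == 0] <- 0
  d <- 1 - sim
  d <- (d + t(d)) / 2          # enforce exact symmetry against FP noise
  d <- pmax(d, 0)
  if (all(rows >= 0)) d <- pmin(d, 1)
  diag(d) <- 0
  new("DistanceMatrix", ids = ids, values = unname(d))
}
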
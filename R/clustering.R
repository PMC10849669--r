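#' Binary UPGMA merge tree with per-node annotations
#'
#' The merge structure follows the `stats::hclust` convention: row i of
#' `merge` records the i-th agglomeration; negative entries are leaf indices
#' (into `leaves`), positive entries are earlier internal nodes. `heights[i]`
#' is the UPGMA node height (half the merging distance), non-decreasing along
#' the merge sequence, so the tree is ultrametric. Each internal node may be
#' annotated with the cosine similarity between its two child clusters'
#' aggregate vectors and with the total mutation count beneath it.
#'
#' @slot leaves ordered leaf ids.
#' @slot merge integer matrix (n-1) x 2, hclust convention.
#' @slot heights numeric vector of n-1 node heights.
#' @slot order integer permutation: left-to-right leaf order of the dendrogram.
#' @slot similarity numeric, per internal node (NA when no vectors available).
#' @slot mutationTotal numeric, per internal node (NA when not applicable).
#' @slot leafTotal numeric, per leaf (NA when not applicable).
#' @seealso [upgma()], [sampleTree()], [doubleCluster()], [toNewick()]
#' @export
setClass("ClusterTree",
  representation(leaves = "character", merge = "matrix", heights = "numeric",
                 order = "integer", similarity = "numeric",
                 mutationTotal = "numeric", leafTotal = "numeric"),
  validity = function(object) {
    n <- length(object@leaves)
    if (n < 2L) return("a tree needs at least 2 leaves")
    if (anyDuplicated(object@leaves)) return("leaf ids must be unique")
    if (nrow(object@merge) != n - 1L || ncol(object@merge) != 2L)
      return("merge must be an (n-1) x 2 matrix")
    if (length(object@heights) != n - 1L)
      return("heights must have n-1 entries")
    if (any(!is.finite(object@heights)) || any(object@heights < 0))
      return("heights must be finite and non-negative")
    if (is.unsorted(object@heights))
      return("heights must be non-decreasing (ultrametric merge sequence)")
    if (!identical(sort(object@order), seq_len(n)))
      return("order must be a permutation of the leaves")
    if (length(object@similarity) != n - 1L ||
        length(object@mutationTotal) != n - 1L)
      return("annotations must have one entry per internal node")
    if (length(object@leafTotal) != n)
      return("leafTotal must have one entry per leaf")
    TRUE
  }
)

setMethod("show", "ClusterTree", function(object) {
  cat(sprintf("ClusterTree (UPGMA): %d leaves, root height %.4g\n",
              length(object@leaves), max(object@heights)))
  if (!all(is.na(object@similarity)))
    cat(sprintf("  annotated: root similarity %.4f, root mutation total %s\n",
                object@similarity[length(object@similarity)],
                format(object@mutationTotal[length(object@mutationTotal)])))
})

#' Left-to-right leaf order of a tree
#' @param tree a [ClusterTree-class].
#' @return character vector of leaf ids in dendrogram order.
#' @export
leafOrder <- function(tree) {
  stopifnot(is(tree, "ClusterTree"))
  tree@leaves[tree@order]
}

#' Node heights of a tree
#' @param tree a [ClusterTree-class].
#' @return numeric vector of the n-1 internal node heights in merge order.
#' @export
nodeHeights <- function(tree) {
  stopifnot(is(tree, "ClusterTree"))
  tree@heights
}

#' Per-node annotations of a tree
#' @param tree a [ClusterTree-class].
#' @return data.frame over internal nodes in merge order: `height`,
#'   `similarity`, `mutationTotal`.
#' @export
nodeAnnotations <- function(tree) {
  stopifnot(is(tree, "ClusterTree"))
  data.frame(height = tree@heights, similarity = tree@similarity,
             mutationTotal = tree@mutationTotal)
}

# Leaf indices (into @leaves) under each internal node, in merge order.
.memberLists <- function(merge) {
  n <- nrow(merge) + 1L
  members <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    get <- function(e) if (e < 0L) -e else members[[e]]
    members[[i]] <- c(get(merge[i, 1L]), get(merge[i, 2L]))
  }
  members
}

# Dendrogram leaf order: left subtree before right subtree, recursively.
.leafOrderFromMerge <- function(merge) {
  n <- nrow(merge) + 1L
  rec <- function(e) if (e < 0L) -e
    else c(rec(merge[e, 1L]), rec(merge[e, 2L]))
  as.integer(rec(n - 1L))
}

#' UPGMA agglomerative clustering
#'
#' Classic unweighted pair group method with arithmetic mean: repeatedly merge
#' the two closest clusters; the merged cluster's distance to any other
#' cluster is the size-weighted arithmetic mean of its members' distances; the
#' new node's height is half the merging distance, so leaves sit at height 0
#' and the tree is ultrametric. Deterministic: among equal-distance pairs the
#' lexicographically smallest (i, j) pair of cluster indices is merged
#' (clusters indexed by creation order, leaves first).
#'
#' @param dist a [DistanceMatrix-class] (or a plain symmetric matrix with
#'   dimnames).
#' @return a [ClusterTree-class]; annotations are NA (no count vectors are
#'   available from a bare distance matrix — see [sampleTree()]).
#' @examples
#' m <- rbind(c(0, 2, 8, 8), c(2, 0, 8, 8), c(8, 8, 0, 4), c(8, 8, 4, 0))
#' rownames(m) <- colnames(m) <- LETTERS[1:4]
#' nodeHeights(upgma(m))  # 1, 2, 4
#' @export
upgma <- function(dist) {
  if (is(dist, "DistanceMatrix")) {
    ids <- dist@ids
    d <- dist@values
  } else {
    d <- as.matrix(dist)
    ids <- rownames(d)
    if (is.null(ids)) ids <- paste0("V", seq_len(nrow(d)))
  }
  if (any(is.na(d)) || any(!is.finite(d)))
    stop("distance matrix contains NA or non-finite values", call. = FALSE)
  n <- length(ids)
  if (n < 2L) stop("need at least 2 items to cluster", call. = FALSE)

  # active clusters keyed by creation index: 1..n leaves, n+1.. internal
  size <- rep(1, n)
  active <- seq_len(n)
  # D over active clusters, names = creation indices
  D <- d
  dimnames(D) <- list(active, active)
  merge <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    m <- length(active)
    # active stays sorted by creation index, so a row-major scan of the upper
    # triangle visits (i, j) pairs in lexicographic order; the first minimum
    # hit is the deterministic tie-break winner
    Du <- D
    Du[lower.tri(Du, diag = TRUE)] <- Inf
    best <- which(t(Du) == min(Du), arr.ind = TRUE)  # t(): row-major scan
    ji <- best[1L, ]                                  # first hit = lex smallest
    i <- ji[2L]; j <- ji[1L]                          # i < j positions
    ci <- active[i]; cj <- active[j]
    hd <- Du[i, j]
    heights[step] <- hd / 2
    merge[step, ] <- c(if (ci <= n) -ci else ci - n,
                       if (cj <= n) -cj else cj - n)
    # size-weighted average distance from the merged cluster to the rest
    others <- setdiff(seq_len(m), c(i, j))
    newd <- (size[ci] * D[i, others] + size[cj] * D[j, others]) /
      (size[ci] + size[cj])
    newIdx <- n + step
    size[newIdx] <- size[ci] + size[cj]
    D <- D[others, others, drop = FALSE]
    D <- rbind(cbind(D, newd), c(newd, 0))
    active <- c(active[others], newIdx)
    dimnames(D) <- list(active, active)
  }
  new("ClusterTree", leaves = ids, merge = merge, heights = heights,
      order = .leafOrderFromMerge(merge),
      similarity = rep(NA_real_, n - 1L),
      mutationTotal = rep(NA_real_, n - 1L),
      leafTotal = rep(NA_real_, n))
}

# Annotate a tree's internal nodes from per-leaf vectors: similarity between
# the two child clusters' aggregate (summed) vectors, and optional totals.
.annotateTree <- function(tree, vectors, withTotals = TRUE) {
  n <- length(tree@leaves)
  members <- .memberLists(tree@merge)
  agg <- function(idx) colSums(vectors[idx, , drop = FALSE])
  sim <- numeric(n - 1L)
  tot <- rep(NA_real_, n - 1L)
  for (i in seq_len(n - 1L)) {
    e1 <- tree@merge[i, 1L]; e2 <- tree@merge[i, 2L]
    m1 <- if (e1 < 0L) -e1 else members[[e1]]
    m2 <- if (e2 < 0L) -e2 else members[[e2]]
    sim[i] <- suppressWarnings(cosineSimilarity(agg(m1), agg(m2)))
    if (withTotals) tot[i] <- sum(vectors[c(m1, m2), ])
  }
  tree@similarity <- sim
  tree@mutationTotal <- tot
  tree@leafTotal <- if (withTotals) rowSums(vectors) else rep(NA_real_, n)
  tree
}

#' Annotated UPGMA tree of the samples of a catalog
#'
#' Clusters samples by UPGMA over pairwise cosine distance of their normalized
#' spectra. Each internal node is annotated with (a) the cosine similarity
#' between the summed raw count vectors of its two child clusters and (b) the
#' total mutation count of the samples beneath it (the node-size annotation of
#' a force-directed tree view).
#'
#' @param catalog a [MutationalCatalog-class] with >= 2 samples.
#' @return an annotated [ClusterTree-class].
#' @export
sampleTree <- function(catalog) {
  stopifnot(is(catalog, "MutationalCatalog"))
  cts <- countMatrix(catalog)
  if (nrow(cts) < 2L) stop("need at least 2 samples", call. = FALSE)
  tot <- rowSums(cts)
  spectra <- cts / ifelse(tot == 0, 1, tot)
  tree <- upgma(pairwiseCosineDistance(spectra))
  .annotateTree(tree, cts, withTotals = TRUE)
}

#' Double clustering of an exposure matrix
#'
#' Independently clusters the rows (samples) and columns (signatures) of the
#' exposure matrix by UPGMA over cosine distance, producing the orderings used
#' to sort an exposure heatmap.
#'
#' @param result an [ExposureResult-class] with >= 2 samples and >= 2
#'   signatures.
#' @return list with `sampleTree`, `signatureTree` ([ClusterTree-class]),
#'   `sampleOrder`, `signatureOrder` (character vectors), and
#'   `sortedExposures` (the exposure matrix in clustered order).
#' @export
doubleCluster <- function(result) {
  stopifnot(is(result, "ExposureResult"))
  e <- exposureMatrix(result)
  if (nrow(e) < 2L || ncol(e) < 2L)
    stop("double clustering needs >= 2 samples and >= 2 signatures",
         call. = FALSE)
  st <- .annotateTree(upgma(pairwiseCosineDistance(e)), e, withTotals = TRUE)
  gt <- .annotateTree(upgma(pairwiseCosineDistance(t(e))), t(e),
                      withTotals = FALSE)
  so <- leafOrder(st)
  go <- leafOrder(gt)
  list(sampleTree = st, signatureTree = gt,
       sampleOrder = so, signatureOrder = go,
       sortedExposures = e[so, go, drop = FALSE])
}

.fmt <- function(x) {
  # fixed-notation representation, trailing zeros trimmed (~1e-12 precision)
  sub("\\.$", "", sub("0+$", "", formatC(x, digits = 12, format = "f")))
}

#' Serialize a tree to Newick
#'
#' Branch length of an edge is parent height minus child height (leaves at
#' height 0), so all branch lengths are non-negative and the tree is
#' ultrametric. Internal nodes are labelled with their cosine-similarity
#' annotation formatted to 4 decimals (omitted when unannotated). The string
#' is terminated by `";"`.
#'
#' @param tree a [ClusterTree-class].
#' @return a single Newick string.
#' @export
toNewick <- function(tree) {
  stopifnot(is(tree, "ClusterTree"))
  h <- tree@heights
  rec <- function(e, parentH) {
    if (e < 0L)
      return(paste0(tree@leaves[-e], ":", .fmt(parentH)))
    lab <- if (is.na(tree@similarity[e])) "" else
      sprintf("%.4f", tree@similarity[e])
    paste0("(", rec(tree@merge[e, 1L], h[e]), ",",
           rec(tree@merge[e, 2L], h[e]), ")", lab,
           if (is.finite(parentH)) paste0(":", .fmt(parentH - h[e])) else "")
  }
  paste0(rec(nrow(tree@merge), Inf), ";")
}

#' Export an annotated tree as nested JSON
#'
#' Nodes carry `id` (leaves), `height`, `similarity` and `mutationTotal`
#' (where annotated) and `children`.
#'
#' @param tree a [ClusterTree-class].
#' @param path optional file path; when given, JSON is written there.
#' @return the JSON string, invisibly when written to a file.
#' @export
treeToJson <- function(tree, path = NULL) {
  stopifnot(is(tree, "ClusterTree"))
  rec <- function(e) {
    if (e < 0L) {
      node <- list(id = tree@leaves[-e], height = 0)
      if (!is.na(tree@leafTotal[-e]))
        node$mutationTotal <- tree@leafTotal[-e]
      return(node)
    }
    node <- list(height = tree@heights[e])
    if (!is.na(tree@similarity[e])) node$similarity <- tree@similarity[e]
    if (!is.na(tree@mutationTotal[e]))
      node$mutationTotal <- tree@mutationTotal[e]
    node$children <- list(rec(tree@merge[e, 1L]), rec(tree@merge[e, 2L]))
    node
  }
  js <- jsonlite::toJSON(rec(nrow(tree@merge)), auto_unbox = TRUE,
                         digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}
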
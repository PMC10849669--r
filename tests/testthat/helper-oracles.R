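# Independent reference implementations used as oracles. These deliberately
# share no code with the package: brute force, naive loops, grid search.

# random small catalog on a toy schema (keeps tests fast)
toySchema <- function(nch = 6) {
  sch <- sbs96Schema()
  new("ChannelSchema", name = sprintf("SBS%d", nch),
      channels = channelLabels(sch)[seq_len(nch)])
}

randomCatalog <- function(nSamples, schema = sbs96Schema(), lambda = 30,
                          meta = NULL) {
  cts <- matrix(rpois(nSamples * length(schema@channels), lambda),
                nrow = nSamples,
                dimnames = list(sprintf("s%02d", seq_len(nSamples)),
                                channelLabels(schema)))
  mutationalCatalog(cts, schema, sampleData = meta)
}

# naive O(n^3) UPGMA: same definition, independent bookkeeping (list of
# member sets, distances recomputed from the ORIGINAL matrix each merge)
naiveUpgma <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))      # leaf index sets
  keys <- seq_len(n)                   # creation index per active cluster
  nodeOf <- -seq_len(n)                # hclust code of each active cluster
  merge <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < best[1]) best <- c(dij, i, j)   # strict < keeps lex-first tie
    }
    i <- best[2]; j <- best[3]
    heights[step] <- best[1] / 2
    merge[step, ] <- c(nodeOf[i], nodeOf[j])
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    nodeOf[i] <- step
    clusters[[j]] <- NULL
    nodeOf <- nodeOf[-j]
    keys <- keys[-j]
  }
  list(merge = merge, heights = heights)
}

# brute-force boxplot stats: sort-based quantiles (linear interpolation done
# by hand), Tukey whiskers, outliers
bruteBoxplot <- function(x) {
  x <- sort(x)
  n <- length(x)
  qat <- function(p) {
    h <- (n - 1) * p
    lo <- floor(h) + 1
    hi <- ceiling(h) + 1
    x[lo] + (h - floor(h)) * (x[hi] - x[lo])
  }
  q1 <- qat(0.25); med <- qat(0.5); q3 <- qat(0.75)
  iqr <- q3 - q1
  inside <- x[x >= q1 - 1.5 * iqr & x <= q3 + 1.5 * iqr]
  wl <- min(inside, q1)   # whiskers never retract past the box edges
  wh <- max(inside, q3)
  list(median = med, q1 = q1, q3 = q3, whiskerLow = wl, whiskerHigh = wh,
       outliers = x[x < wl | x > wh])
}

# grid search over nonnegative coefficient vectors, step 0.01, for tiny NNLS
# (affordable for k <= 2; higher k is covered by exact support enumeration)
gridNnlsObjective <- function(A, b, upper, step = 0.01) {
  grids <- rep(list(seq(0, upper, by = step)), ncol(A))
  xs <- as.matrix(expand.grid(grids))
  resid <- xs %*% t(A) - matrix(b, nrow(xs), length(b), byrow = TRUE)
  min(rowSums(resid^2))
}

# exact NNLS oracle by support enumeration: the optimum is the unconstrained
# least-squares solution on some subset of the columns, so minimizing over
# all 2^k subsets with a nonnegative solution is exact (k <= 4 here)
enumNnlsObjective <- function(A, b) {
  k <- ncol(A)
  best <- sum(b^2)   # empty support
  for (code in seq_len(2^k - 1)) {
    S <- which(bitwAnd(code, 2^(seq_len(k) - 1)) > 0)
    x <- qr.coef(qr(A[, S, drop = FALSE]), b)
    if (anyNA(x) || any(x < -1e-12)) next
    obj <- sum((b - A[, S, drop = FALSE] %*% x)^2)
    if (obj < best) best <- obj
  }
  best
}

# tree distance between two leaves = sum of branch lengths on the path;
# for an ultrametric tree this is 2 * height of the lowest common ancestor
lcaHeight <- function(tree, leafA, leafB) {
  members <- msigkit:::.memberLists(tree@merge)
  ia <- match(leafA, tree@leaves); ib <- match(leafB, tree@leaves)
  for (k in seq_along(members))
    if (ia %in% members[[k]] && ib %in% members[[k]]) return(tree@heights[k])
  stop("no common ancestor found")
}
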
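# canonical view of a merge sequence: per step, the height and the sorted
# leaf-member set of the newly formed cluster
canonicalMerges <- function(merge, heights) {
  members <- msigkit:::.memberLists(merge)
  lapply(seq_along(heights), function(i)
    list(height = heights[i], members = sort(members[[i]])))
}

test_that("two items merge at half their distance", {
  m <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tree <- upgma(m)
  expect_equal(nodeHeights(tree), 1.5)
  expect_setequal(leafOrder(tree), c("A", "B"))
})

test_that("hand-worked 4-leaf example gives heights 1, 2, 4", {
  m <- rbind(c(0, 2, 8, 8), c(2, 0, 8, 8), c(8, 8, 0, 4), c(8, 8, 4, 0))
  rownames(m) <- colnames(m) <- c("A", "B", "C", "D")
  tree <- upgma(m)
  expect_equal(nodeHeights(tree), c(1, 2, 4))
  cm <- canonicalMerges(tree@merge, tree@heights)
  expect_equal(cm[[1]]$members, c(1, 2))   # (A,B) first
  expect_equal(cm[[2]]$members, c(3, 4))   # then (C,D)
  expect_equal(cm[[3]]$members, 1:4)
  expect_error(upgma(matrix(c(0, NA, NA, 0), 2)), "NA")
})

test_that("upgma agrees with a naive O(n^3) oracle on random matrices", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(3:8, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 2)
    d <- d + t(d)
    dimnames(d) <- list(paste0("L", 1:n), paste0("L", 1:n))
    tree <- upgma(d)
    oracle <- naiveUpgma(d)
    expect_equal(canonicalMerges(tree@merge, tree@heights),
                 canonicalMerges(oracle$merge, oracle$heights),
                 tolerance = 1e-9)
  }
})

test_that("upgma heights match hclust average linkage", {
  set.seed(78)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2)
    d <- d + t(d)
    dimnames(d) <- list(paste0("L", 1:n), paste0("L", 1:n))
    tree <- upgma(d)
    hc <- hclust(as.dist(d), method = "average")
    # hclust heights are merge distances; UPGMA node heights are half that
    expect_equal(sort(nodeHeights(tree)) * 2, sort(hc$height),
                 tolerance = 1e-9)
  }
})

test_that("trees are ultrametric: path length = 2 x LCA height", {
  set.seed(79)
  n <- 7
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.2, 1.5)
  d <- d + t(d)
  dimnames(d) <- list(paste0("L", 1:n), paste0("L", 1:n))
  tree <- upgma(d)
  expect_false(is.unsorted(nodeHeights(tree)))
  # read path lengths back from the Newick serialization
  skip_if_not_installed("ape")
  phy <- ape::read.tree(text = toNewick(tree))
  pd <- ape::cophenetic.phylo(phy)
  for (a in tree@leaves) for (b in setdiff(tree@leaves, a))
    expect_equal(pd[a, b], 2 * lcaHeight(tree, a, b), tolerance = 1e-9)
})

test_that("sampleTree annotations: totals conserve, similarities in [0,1]", {
  set.seed(80)
  sim <- generateCatalog(simulationSpec(nSamples = 10, seed = 81))
  tree <- sampleTree(sim$catalog)
  ann <- nodeAnnotations(tree)
  expect_equal(ann$mutationTotal[nrow(ann)], sum(countMatrix(sim$catalog)))
  # every internal node total = sum of its children's totals
  members <- msigkit:::.memberLists(tree@merge)
  leafTot <- rowSums(countMatrix(sim$catalog))
  for (i in seq_len(nrow(ann)))
    expect_equal(ann$mutationTotal[i], sum(leafTot[members[[i]]]))
  expect_true(all(ann$similarity >= 0 & ann$similarity <= 1 + 1e-12))
  expect_equal(unname(tree@leafTotal), unname(leafTot))
  expect_equal(tree@leafTotal[sampleIds(sim$catalog)[3]],
               sampleSummary(sim$catalog)$total[3], ignore_attr = TRUE)
})

test_that("identical samples merge first with root similarity 1 at n = 2", {
  sch <- sbs96Schema()
  row <- rpois(96, 10)
  m <- rbind(a = row, b = row)
  m["b", ] <- row            # identical spectra, different scale below
  m2 <- rbind(a = row * 2, b = row)    # totals 2x and 1x, same direction
  colnames(m2) <- channelLabels(sch)
  tree <- sampleTree(mutationalCatalog(m2, sch))
  ann <- nodeAnnotations(tree)
  expect_equal(ann$similarity, 1, tolerance = 1e-12)
  expect_equal(ann$mutationTotal, sum(m2))
  expect_equal(nodeHeights(tree), 0, tolerance = 1e-12)
})

test_that("doubleCluster orders are permutations; identical samples adjacent", {
  sim <- generateCatalog(simulationSpec(nSamples = 8, nSignatures = 4,
                                        seed = 82))
  res <- refitExposures(sim$catalog, sim$signatures)
  e <- exposureMatrix(res)
  e["sample003", ] <- e["sample007", ]          # plant identical samples
  res2 <- exposureResult(e, rnormValues(res))
  dc <- doubleCluster(res2)
  expect_setequal(dc$sampleOrder, sampleIds(res2))
  expect_setequal(dc$signatureOrder, signatureIds(res2))
  pos <- match(c("sample003", "sample007"), dc$sampleOrder)
  expect_equal(abs(diff(pos)), 1)
  expect_equal(dim(dc$sortedExposures), dim(e))
  expect_equal(dc$sortedExposures, e[dc$sampleOrder, dc$signatureOrder])
})

test_that("tree topology is invariant under input permutation (tie-free)", {
  set.seed(83)
  sim <- generateCatalog(simulationSpec(nSamples = 7, seed = 84))
  cts <- countMatrix(sim$catalog)
  t1 <- sampleTree(mutationalCatalog(cts, sbs96Schema()))
  perm <- sample(nrow(cts))
  t2 <- sampleTree(mutationalCatalog(cts[perm, ], sbs96Schema()))
  cm <- function(tr) lapply(canonicalMerges(tr@merge, tr@heights), function(x)
    list(height = x$height, members = sort(tr@leaves[x$members])))
  expect_equal(cm(t1), cm(t2), tolerance = 1e-12)
})

test_that("Newick export round-trips leaves, heights and labels", {
  skip_if_not_installed("ape")
  # 2-leaf reference string
  m <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  sch <- sbs96Schema()
  cts <- rbind(A = rep(1L, 96), B = rep(1L, 96))
  colnames(cts) <- channelLabels(sch)
  tr2 <- sampleTree(mutationalCatalog(cts, sch))
  expect_equal(toNewick(tr2), "(A:0,B:0)1.0000;")
  set.seed(85)
  sim <- generateCatalog(simulationSpec(nSamples = 9, seed = 86))
  tree <- sampleTree(sim$catalog)
  nwk <- toNewick(tree)
  expect_true(endsWith(nwk, ";"))
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, sampleIds(sim$catalog))
  expect_true(all(phy$edge.length >= 0))
  # leaf depth below the root = root height, for every leaf (ultrametric)
  depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  expect_equal(unname(depths), rep(max(nodeHeights(tree)), 9),
               tolerance = 1e-9)
  # internal labels carry the 4-decimal similarity annotations
  expect_setequal(phy$node.label,
                  sprintf("%.4f", nodeAnnotations(tree)$similarity))
})

test_that("annotated JSON export nests children with conserved totals", {
  sim <- generateCatalog(simulationSpec(nSamples = 5, seed = 87))
  tree <- sampleTree(sim$catalog)
  js <- jsonlite::fromJSON(treeToJson(tree), simplifyVector = FALSE)
  checkNode <- function(node) {
    if (!is.null(node$children)) {
      kids <- vapply(node$children, checkNode, 0)
      expect_equal(node$mutationTotal, sum(kids))
      node$mutationTotal
    } else node$mutationTotal
  }
  expect_equal(checkNode(js), sum(countMatrix(sim$catalog)))
})
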
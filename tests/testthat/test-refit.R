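test_that("nnlsSolve handles identity and zero targets exactly", {
  A <- diag(4)
  b <- c(2, 0, 5, 1)
  fit <- nnlsSolve(A, b)
  expect_equal(fit$coefficients, b)
  expect_equal(fit$rnorm, 0)
  fit0 <- nnlsSolve(matrix(runif(12), 4), rep(0, 4))
  expect_equal(fit0$coefficients, rep(0, 3))
  expect_equal(fit0$rnorm, 0)
})

test_that("negative components are clamped at zero, not projected", {
  # orthogonal design, target [3, -1]: unconstrained solution is (3, -1);
  # NNLS must clamp the second coefficient and pay rnorm = 1
  A <- cbind(c(1, 0), c(0, 1))
  fit <- nnlsSolve(A, c(3, -1))
  expect_equal(fit$coefficients, c(3, 0))
  expect_equal(fit$rnorm, 1)
  # same conclusion under column scaling
  fit2 <- nnlsSolve(cbind(c(2, 0), c(0, 0.5)), c(3, -1))
  expect_equal(fit2$coefficients, c(1.5, 0))
  expect_equal(fit2$rnorm, 1)
})

test_that("nnlsSolve validates inputs", {
  expect_error(nnlsSolve(matrix(c(1, NA), 2, 1), c(1, 2)), "non-finite")
  expect_error(nnlsSolve(matrix(1, 2, 1), c(1, 2, 3)), "dimension mismatch")
  expect_error(nnlsSolve(cbind(c(1, 1), c(0, 0)), c(1, 2)), "all-zero column")
})

test_that("objective never beats a dense grid search and KKT holds", {
  set.seed(99)
  for (rep in 1:200) {
    nch <- sample(2:6, 1)
    k <- sample(1:4, 1)
    A <- matrix(runif(nch * k), nch, k)
    b <- runif(nch, 0, 2)
    fit <- nnlsSolve(A, b)
    # KKT: gradient of 0.5*||Ax-b||^2 is -A'(b-Ax) = -w
    w <- drop(crossprod(A, b - A %*% fit$coefficients))
    tol <- 1e-8 * max(abs(crossprod(A, b)), 1)
    expect_true(all(w <= tol))                       # dual feasibility
    expect_true(all(abs(w[fit$coefficients > 0]) <= tol))  # complementarity
    expect_equal(fit$rnorm,
                 sum((b - A %*% fit$coefficients)^2), tolerance = 1e-10)
    # exact support-enumeration oracle for every instance
    expect_equal(fit$rnorm, enumNnlsObjective(A, b), tolerance = 1e-8)
    if (k <= 2) {   # dense grid is affordable only in low dimension
      best <- gridNnlsObjective(A, b, upper = 3, step = 0.01)
      expect_lte(fit$rnorm, best + 1e-9)
    }
  }
})

test_that("agrees with the unconstrained solution when it is nonnegative", {
  set.seed(100)
  tried <- 0
  for (rep in 1:100) {
    nch <- sample(3:8, 1)
    k <- sample(1:3, 1)
    A <- matrix(runif(nch * k, 0.1, 1), nch, k)
    xTrue <- runif(k, 0.5, 2)
    b <- drop(A %*% xTrue) + rnorm(nch, sd = 0.01)
    uncon <- qr.coef(qr(A), b)
    if (all(uncon >= 0)) {
      tried <- tried + 1
      fit <- nnlsSolve(A, b)
      expect_equal(fit$coefficients, unname(uncon), tolerance = 1e-8)
    }
  }
  expect_gt(tried, 20)   # the case actually occurred often enough
})

test_that("refitExposures recovers exactly constructed noiseless exposures", {
  # rational signature profiles + exposures that are multiples of the profile
  # denominators make the expected counts exactly integral, so the noiseless
  # catalog is exactly representable and NNLS must recover the ground truth
  sch <- sbs96Schema()
  set.seed(18)
  M <- matrix(rpois(96 * 4, 3) + 1L, 96, 4,
              dimnames = list(channelLabels(sch), paste0("S", 1:4)))
  P <- sweep(M, 2, colSums(M), "/")
  sigs <- signatureSet(P, sch)
  mult <- matrix(sample(0:30, 6 * 4, replace = TRUE), 6, 4,
                 dimnames = list(sprintf("c%d", 1:6), colnames(M)))
  eTrue <- sweep(mult, 2, colSums(M), "*")       # exposures in count units
  counts <- eTrue %*% t(P)                        # = mult %*% t(M): integral
  expect_true(all(abs(counts - round(counts)) < 1e-9))
  cat <- mutationalCatalog(round(counts), sch)
  res <- refitExposures(cat, sigs)
  expect_equal(exposureMatrix(res), eTrue, tolerance = 1e-6)
  expect_true(all(rnormValues(res) < 1e-8))
  # zero-count sample: zero exposures, zero rnorm
  z <- mutationalCatalog(matrix(0L, 1, 96, dimnames = list("z", rownames(P))),
                         sch)
  rz <- refitExposures(z, sigs)
  expect_equal(unname(exposureMatrix(rz)[1, ]), rep(0, 4))
  expect_equal(unname(rnormValues(rz)), 0)
})

test_that("rnorm equals the squared residual norm and is deterministic", {
  sim <- generateCatalog(simulationSpec(nSamples = 5, seed = 23))
  res1 <- refitExposures(sim$catalog, sim$signatures)
  res2 <- refitExposures(sim$catalog, sim$signatures)
  expect_identical(exposureMatrix(res1), exposureMatrix(res2))
  P <- signatureProfiles(sim$signatures)
  cts <- countMatrix(sim$catalog)
  for (i in seq_len(nrow(cts))) {
    resid <- cts[i, ] - drop(P %*% exposureMatrix(res1)[i, ])
    expect_equal(unname(rnormValues(res1)[i]), sum(resid^2),
                 tolerance = 1e-6)
  }
})

test_that("duplicating a signature never increases any sample's rnorm", {
  sim <- generateCatalog(simulationSpec(nSamples = 8, nSignatures = 3,
                                        exposuresActivePerSample = 2,
                                        seed = 29))
  base <- refitExposures(sim$catalog, sim$signatures)
  P <- signatureProfiles(sim$signatures)
  P2 <- cbind(P, dup = P[, 1])
  colnames(P2) <- c(colnames(P), "dup")
  sigs2 <- signatureSet(P2, channelSchema(sim$signatures))
  wider <- refitExposures(sim$catalog, sigs2)
  expect_true(all(rnormValues(wider) <= rnormValues(base) + 1e-6))
})

test_that("schema mismatch is reported with the first differing channel", {
  sim <- generateCatalog(simulationSpec(nSamples = 2, seed = 31))
  sch <- channelSchema(sim$catalog)
  swapped <- channelLabels(sch)
  swapped[1:2] <- swapped[2:1]
  badSchema <- new("ChannelSchema", name = "SBS96", channels = swapped)
  P <- signatureProfiles(sim$signatures)[swapped, ]
  badSigs <- signatureSet(P, badSchema)
  expect_error(refitExposures(sim$catalog, badSigs),
               "first differing channel: A\\[C>A\\]A")
})

test_that("relativeExposures fractions are sorted, normalized, scale-invariant", {
  e <- matrix(c(30, 10, 0), 1, dimnames = list("s", c("S1", "S2", "S3")))
  res <- exposureResult(e, 0)
  rel <- relativeExposures(res, "s")
  expect_equal(rel$fraction, c(0.75, 0.25, 0))
  expect_equal(rel$signature, c("S1", "S2", "S3"))
  # single nonzero activity
  e1 <- matrix(c(0, 5), 1, dimnames = list("s", c("A", "B")))
  expect_equal(relativeExposures(exposureResult(e1, 0), "s")$fraction[1], 1)
  # scale invariance
  rel10 <- relativeExposures(exposureResult(e * 10, 0), "s")
  expect_equal(rel10$fraction, rel$fraction)
  # all-zero sample warns, fractions zero
  ez <- matrix(0, 1, 2, dimnames = list("s", c("A", "B")))
  expect_warning(relz <- relativeExposures(exposureResult(ez, 0), "s"),
                 "no positive activity")
  expect_equal(relz$fraction, c(0, 0))
  expect_error(relativeExposures(res, "nope"), "unknown sample")
})
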
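test_that("participation-ratio anchors", {
  expect_equal(participationRatio(rep(1, 16)), 16)
  expect_equal(participationRatio(c(1, rep(0, 15))), 1)
  expect_equal(participationRatio(c(3, 1)), 1.6)
  ## m equal eigenvalues among zeros -> m
  for (m in 1:6) expect_equal(participationRatio(c(rep(2, m), rep(0, 10))), m)
  expect_error(participationRatio(rep(0, 5)), "all-zero")
  expect_error(participationRatio(c(1, -0.5)), "negative")
  ## tiny negative numerical eigenvalues are floored
  expect_equal(participationRatio(c(1, 1, -1e-12)), 2, tolerance = 1e-9)
})

test_that("dimensionality is invariant to channel permutation and global scaling", {
  set.seed(31)
  X <- matrix(rnorm(200 * 8), 200) %*% matrix(rnorm(64), 8)
  d0 <- prpdecode:::dataDim(X)
  expect_equal(prpdecode:::dataDim(X[, sample(8)]), d0, tolerance = 1e-9)
  expect_equal(prpdecode:::dataDim(3.7 * X), d0, tolerance = 1e-9)
})

test_that("noiseless rank-m mixing with whitened sources has dimension exactly m", {
  set.seed(32)
  n <- 60; M <- 16
  for (m in 1:6) {
    L <- matrix(rnorm(n * m), n)
    ## whiten so the sample covariance of the sources is exactly identity
    L <- scale(L, scale = FALSE)
    L <- L %*% solve(chol(cov(L)))
    V <- qr.Q(qr(matrix(rnorm(M * m), M)))
    X <- L %*% t(V)
    lam <- eigen(cov(X), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(lam > 1e-9), m)
    expect_equal(participationRatio(lam), m, tolerance = 1e-6)
  }
})

test_that("i.i.d. noise across 16 channels has near-full dimensionality", {
  set.seed(33)
  X <- matrix(rnorm(500 * 16), 500)
  expect_equal(prpdecode:::dataDim(X), 16, tolerance = 1.5 / 16)
})

test_that("isotropic sensor noise monotonically raises dimensionality toward M", {
  set.seed(34)
  n <- 300; M <- 12; m <- 3
  L <- matrix(rnorm(n * m), n)
  V <- qr.Q(qr(matrix(rnorm(M * m), M)))
  noise <- matrix(rnorm(n * M), n)
  dims <- vapply(c(0, 0.2, 0.5, 1, 2), function(s)
    prpdecode:::dataDim(L %*% t(V) + s * noise), numeric(1))
  expect_true(all(diff(dims) > 0))
  expect_lt(dims[1], m + 1)
  expect_gt(dims[length(dims)], M - 2)
})

test_that("latent collapse during odor lowers the normalized dimensionality", {
  fx <- smallProficientChain()
  dtc <- dimTimecourse(fx$prp, "proficient", groupByOdorant = FALSE,
                       config = fx$cfg)
  cv <- dimCurves(dtc)
  odor <- cv$timebin_s >= 0.5 & cv$timebin_s < 2.5
  base <- cv$timebin_s >= -1 & cv$timebin_s < 0
  expect_lt(mean(cv$normalized_dim[odor]), 1)
  expect_equal(mean(cv$normalized_dim[base]), 1, tolerance = 0.15)
  expect_lt(mean(cv$dim[odor]), mean(cv$dim[base]))
})

## build a minimal PrpTensor by hand
makePrp <- function(nT, nEl, odorant, seed = 1, nb = 8) {
  set.seed(seed)
  tb <- gridCentersForTest(c(-0.4, 0.4), 0.1)
  vals <- array(rnorm(nT * nEl * nb), c(nT, nEl, nb))
  new("PrpTensor", valuesDb = vals, reference = "peak",
      band = bandSpec("high_gamma", 65, 95), timebinsS = tb,
      odorWindowMeanDb = matrix(0, nT, nEl),
      trialInfo = data.frame(odorant = odorant,
                             stage = rep("proficient", nT),
                             outcome = ifelse(odorant == "S+", "Hit", "CR")),
      referencePhases = data.frame(electrode = seq_len(nEl),
                                   phase_deg = 100))
}

test_that("pooling truncates to the minimum per-odorant trial count and concatenates channels", {
  p1 <- makePrp(30 + 30, 4, rep(c("S+", "S-"), c(30, 30)), seed = 1)
  p2 <- makePrp(25 + 40, 4, rep(c("S+", "S-"), c(25, 40)), seed = 2)
  p3 <- makePrp(40 + 25, 4, rep(c("S+", "S-"), c(40, 25)), seed = 3)
  pooled <- poolSessions(list(p1, p2, p3))
  info <- trialData(pooled)
  expect_equal(sum(info$odorant == "S+"), 25)
  expect_equal(sum(info$odorant == "S-"), 25)
  expect_equal(dim(prpValues(pooled))[2], 12)
  ## single-session pooling is the identity
  expect_identical(poolSessions(list(p1)), p1)
})

test_that("pooling duplicated sessions adds channels but no dimensions", {
  p <- makePrp(40, 5, rep(c("S+", "S-"), each = 20), seed = 4)
  pooled <- poolSessions(list(p, p))
  j <- 3
  X1 <- prpValues(p)[, , j]
  X2 <- prpValues(pooled)[, , j]
  expect_equal(ncol(X2), 10)
  expect_equal(prpdecode:::dataDim(X2), prpdecode:::dataDim(X1),
               tolerance = 1e-9)
})
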
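test_that("modulation index anchors: uniform, delta and two-bin distributions", {
  fx <- phaseEnvFixture()
  d <- pacDistribution(fx$phaseDeg, fx$envelope)
  expect_lt(d@mi, 1e-9)
  expect_equal(sum(d@p), 1, tolerance = 1e-12)

  ## all envelope mass in one phase bin -> MI = 1
  width <- 360 / 51
  inBin <- fx$phaseDeg >= 10 * width & fx$phaseDeg < 11 * width
  d1 <- pacDistribution(fx$phaseDeg, as.numeric(inBin))
  expect_equal(d1@mi, 1)
  expect_equal(d1@peakPhaseDeg, (10 + 0.5) * width)

  ## two equal bins -> MI = 1 - ln2/ln51
  two <- as.numeric(inBin | (fx$phaseDeg >= 30 * width &
                               fx$phaseDeg < 31 * width))
  ## equalize bin means: bins have slightly different occupancy, so build
  ## p directly through modulationIndex
  p <- numeric(51); p[c(3, 40)] <- 0.5
  expect_equal(modulationIndex(p), 1 - log(2) / log(51),
               tolerance = 1e-9)
  d2 <- pacDistribution(fx$phaseDeg, two)
  expect_equal(d2@mi, 1 - log(2) / log(51), tolerance = 1e-6)
})

test_that("modulationIndex validates its input", {
  expect_error(modulationIndex(c(0.5, 0.4)), "not normalized")
  expect_error(modulationIndex(c(1.2, -0.2)), "nonnegative")
  expect_equal(modulationIndex(rep(1 / 51, 51)), 0)
})

test_that("empty phase bins are rejected with guidance", {
  ph <- rep(10, 100)   # only one bin visited
  expect_error(pacDistribution(ph, rep(1, 100)), "longer input")
})

test_that("MI is invariant to positive envelope scaling", {
  set.seed(1)
  fx <- phaseEnvFixture(fun = function(ph) 1 + 0.4 * cos(ph * pi / 180))
  base <- pacDistribution(fx$phaseDeg, fx$envelope)@mi
  for (k in c(1e-6, 0.5, 3, 1e4)) {
    expect_equal(pacDistribution(fx$phaseDeg, k * fx$envelope)@mi, base,
                 tolerance = 1e-12)
  }
})

test_that("MI increases with von Mises burst concentration", {
  fx <- phaseEnvFixture()
  mis <- vapply(c(0, 0.5, 1, 2, 4), function(kappa) {
    env <- exp(kappa * cos((fx$phaseDeg - 180) * pi / 180))
    pacDistribution(fx$phaseDeg, env)@mi
  }, numeric(1))
  expect_true(all(diff(mis) > 0))
})

test_that("vectorized MI equals a brute-force per-sample histogram loop", {
  set.seed(7)
  n <- 5000
  ph <- runif(n, 0, 360)
  env <- rexp(n) * (1 + 0.5 * cos(ph * pi / 180))
  d <- pacDistribution(ph, env)
  ## brute force: explicit loop over samples
  sums <- numeric(51); cnts <- numeric(51)
  for (i in seq_len(n)) {
    b <- min(floor(ph[i] / (360 / 51)) + 1, 51)
    sums[b] <- sums[b] + env[i]
    cnts[b] <- cnts[b] + 1
  }
  p <- (sums / cnts) / sum(sums / cnts)
  h <- -sum(p[p > 0] * log(p[p > 0]))
  expect_equal(d@p, p, tolerance = 1e-12)
  expect_equal(d@mi, (log(51) - h) / log(51), tolerance = 1e-12)
})

test_that("circular phase shifts move the peak and leave MI unchanged", {
  fx <- phaseEnvFixture(fun = function(ph) 1 + 0.4 * cos((ph - 90) * pi / 180))
  d0 <- pacDistribution(fx$phaseDeg, fx$envelope)
  width <- 360 / 51
  for (k in c(3, 17, 33)) {
    dk <- pacDistribution((fx$phaseDeg + k * width) %% 360, fx$envelope)
    expect_equal(dk@mi, d0@mi, tolerance = 1e-9)
    expect_equal(dk@peakPhaseDeg,
                 (d0@peakPhaseDeg + k * width) %% 360, tolerance = 1e-9)
  }
})

test_that("peak-angle variance: anchors and limits", {
  expect_equal(peakAngleVariance(rep(123, 10)), 0)
  grid <- seq(0, 359.999, length.out = 1000)
  expect_gte(peakAngleVariance(grid), 0.99)
  expect_equal(peakAngleVariance(c(0, 90)), 1 - sqrt(2) / 2,
               tolerance = 1e-12)
  expect_error(peakAngleVariance(numeric(0)), "at least 2")
  expect_error(peakAngleVariance(5), "at least 2")
  ## linear alternative: deg^2 variance of unwrapped deviations
  expect_equal(peakAngleVariance(c(350, 10), method = "linear_deg2"),
               var(c(-10, 10)), tolerance = 1e-9)
})

test_that("sessionPac recovers generator coupling and requires S+ trials", {
  fx <- smallProficientChain()
  pac <- fx$pac
  truthPhase <- 120
  gp <- pac$groups[pac$groups$odorant == "S+", ]
  dPhase <- abs(((gp$peak_deg - truthPhase + 180) %% 360) - 180)
  expect_lt(dPhase, 15)
  miSplus <- mean(pac$trials$mi[pac$trials$odorant == "S+"])
  expect_lt(abs(miSplus - 0.02) / 0.02, 0.3)
  ## S+ phase-locked trials have smaller peak-angle variance than S-
  expect_lt(gp$peak_angle_variance,
            pac$groups$peak_angle_variance[pac$groups$odorant == "S-"])

  tt <- fx$sim$trials
  onlySminus <- new("TrialTable",
                    trials = tt@trials[tt@trials$odorant == "S-", ],
                    percentCorrect = tt@percentCorrect[tt@trials$odorant == "S-"],
                    stage = tt@stage[tt@trials$odorant == "S-"])
  expect_error(sessionPac(fx$sim$session, onlySminus, config = fx$cfg),
               "S\\+")
})
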
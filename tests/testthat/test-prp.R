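test_that("reference crossings are spaced one carrier period apart", {
  rate <- 2000
  t <- seq(0, 2, by = 1 / rate)
  phase <- (360 * 8 * t) %% 360
  ct0 <- referenceCrossingTimes(phase, 0, rate)
  expect_true(all(abs(diff(ct0) - 0.125) < 0.001))
  ct180 <- referenceCrossingTimes(phase, 180, rate)
  ## 180-degree crossings sit half a period offset from the 0-degree grid
  expect_true(all(abs(ct0 %% 0.125) < 0.001 |
                    abs(ct0 %% 0.125 - 0.125) < 0.001))
  expect_true(all(abs(ct180 %% 0.125 - 0.0625) < 0.001))
})

test_that("a deleted carrier cycle yields exactly one crossing per completed cycle", {
  rate <- 2000
  t <- seq(0, 1, by = 1 / rate)
  phase <- (360 * 8 * t) %% 360
  ## drop one full cycle of samples (simulated dropout); phase remains
  ## continuous across the splice
  cyc <- which(t >= 0.25 & t < 0.375)
  spliced <- phase[-cyc]
  ct <- referenceCrossingTimes(spliced, 90, rate)
  expect_equal(length(ct), length(referenceCrossingTimes(phase, 90, rate)) - 1)
})

test_that("PRP of a constant-amplitude fast band is flat", {
  rate <- 2000
  dur <- 10
  t <- seq(0, dur, length.out = dur * rate)
  sig <- 20 * cos(2 * pi * 8 * t) + 5 * cos(2 * pi * 80 * t)
  ses <- lfpSession(matrix(sig, nrow = 1), rate = rate,
                    sessionId = "flat", subjectId = "toy")
  tt <- trialTable(data.frame(trial_start_s = 2, odor_on_s = 3,
                              odorant = "S+", outcome = "Hit",
                              reinforced = TRUE))
  cfg <- analysisConfig(trialWindowS = c(-1, 2.5), odorWindowS = c(0, 2))
  v <- trialPrp(ses, tt, 1, 1, "high_gamma", 0, cfg)
  expect_lt(sd(v), 0.5)
})

test_that("coupled bursts raise peak-referenced over trough-referenced PRP; uncoupled signals do not", {
  rate <- 2000
  prpDiff <- function(coupling) {
    sim <- simulatePacSignal(simulationConfig(coupling = coupling,
                                              durationS = 10, rate = rate))
    ses <- lfpSession(matrix(sim$signal, nrow = 1), rate = rate,
                      sessionId = coupling, subjectId = "toy")
    tt <- trialTable(data.frame(trial_start_s = 2.5, odor_on_s = 3.5,
                                odorant = "S+", outcome = "Hit",
                                reinforced = TRUE))
    cfg <- analysisConfig(trialWindowS = c(-1, 2.5), odorWindowS = c(0, 2),
                          bands = within(defaultBands(), rm(theta_wide)))
    peak <- trialPrp(ses, tt, 1, 1, "low_gamma_sim", 180, cfg)
    trough <- trialPrp(ses, tt, 1, 1, "low_gamma_sim", 0, cfg)
    peak - trough
  }
  dCoupled <- prpDiff("burst")
  expect_gte(mean(dCoupled > 0), 0.95)
  dNone <- prpDiff("none")
  expect_lt(abs(mean(dNone)), 0.5)
})

test_that("session PRP recovers the configured odor-gain contrast", {
  fx <- smallProficientChain()
  prp <- fx$prp
  info <- trialData(prp)
  tb <- timeBins(prp)
  base <- apply(prpValues(prp)[, , tb >= -1 & tb < 0, drop = FALSE],
                c(1, 2), mean)
  d <- rowMeans(prp@odorWindowMeanDb - base)
  contrast <- mean(d[info$odorant == "S+"]) - mean(d[info$odorant == "S-"])
  ## configured +6 / -6 dB amplitude gains; peak-referenced sampling adds
  ## the S- phase-jitter penalty, so expect at least the configured 12 dB
  expect_gt(contrast, 10)
  expect_lt(contrast, 20)
})

test_that("group PRP summaries average trial summaries and respect group sizes", {
  fx <- smallProficientChain()
  smry <- prpSummary(fx$prp, fx$cfg)
  expect_true(all(c("reference", "electrode", "odorant", "stage",
                    "mean_db", "lo_db", "hi_db") %in% names(smry)))
  info <- trialData(fx$prp)
  sel <- info$odorant == "S+" & info$stage == "proficient"
  expect_equal(smry$mean_db[smry$odorant == "S+" & smry$electrode == 1],
               mean(fx$prp@odorWindowMeanDb[sel, 1]))
  expect_true(all(smry$lo_db <= smry$mean_db & smry$mean_db <= smry$hi_db))
})

test_that("PRP values do not depend on trial order", {
  fx <- smallProficientChain()
  tt <- fx$sim$trials
  n <- nrow(tt@trials)
  perm <- c(2, 1, seq(3, n))
  ttPerm <- new("TrialTable", trials = tt@trials[perm, ],
                percentCorrect = tt@percentCorrect[perm],
                stage = tt@stage[perm])
  prpPerm <- sessionPrp(fx$sim$session, ttPerm, "high_gamma", "peak",
                        fx$cfg, pac = fx$pac)
  expect_equal(prpValues(prpPerm)[1, , ], prpValues(fx$prp)[2, , ])
  expect_equal(prpValues(prpPerm)[2, , ], prpValues(fx$prp)[1, , ])
})

test_that("swapping odorant valence swaps the PRP group means (reversal bookkeeping)", {
  fx <- smallProficientChain()
  prp <- fx$prp
  swapped <- prp
  swapped@trialInfo$odorant <- ifelse(prp@trialInfo$odorant == "S+",
                                      "S-", "S+")
  s1 <- prpSummary(prp, fx$cfg)
  s2 <- prpSummary(swapped, fx$cfg)
  m1 <- tapply(s1$mean_db, s1$odorant, mean)
  m2 <- tapply(s2$mean_db, s2$odorant, mean)
  expect_equal(unname(m1["S+"]), unname(m2["S-"]))
  expect_equal(unname(m1["S-"]), unname(m2["S+"]))
})

test_that("peak-minus-trough PRP grows with burst depth at fixed seed", {
  rate <- 2000
  gap <- vapply(c(0.3, 1, 3), function(amp) {
    sim <- simulatePacSignal(simulationConfig(coupling = "burst",
                                              burstAmp = amp,
                                              durationS = 8, rate = rate))
    lo <- bandpassFilter(sim$signal, bandSpec("theta", 6, 14), rate)
    phase <- prpdecode:::wrap360(Arg(analyticSignal(lo)) * 180 / pi)
    power <- morletBandPower(sim$signal, rate, "low_gamma_sim")
    at <- function(ref) {
      ct <- referenceCrossingTimes(phase, ref, rate)
      mean(power[pmin(pmax(round(ct * rate) + 1, 1), length(power))])
    }
    at(180) - at(0)
  }, numeric(1))
  expect_true(all(diff(gap) > 0))
  expect_gt(gap[3], 1)
})
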
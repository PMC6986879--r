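test_that("sessions round-trip through the on-disk layout", {
  sim <- toySession()
  d1 <- file.path(tempdir(), "ses-a")
  d2 <- file.path(tempdir(), "ses-b")
  saveSession(sim$session, sim$trials, d1)
  loaded <- loadSession(d1)
  ## float32 storage: values match to single precision
  expect_equal(lfpSamples(loaded$session), lfpSamples(sim$session),
               tolerance = 1e-6)
  expect_equal(trialData(loaded$trials)$odorant,
               trialData(sim$trials)$odorant)
  expect_equal(trialData(loaded$trials)$outcome,
               trialData(sim$trials)$outcome)
  expect_equal(trialData(loaded$trials)$odor_on_s,
               trialData(sim$trials)$odor_on_s)
  expect_equal(trialData(loaded$trials)$lick_times,
               trialData(sim$trials)$lick_times, tolerance = 1e-12)

  ## save(load(save(x))) is byte-identical to save(x)
  saveSession(loaded$session, loaded$trials, d2)
  for (f in c("metadata.json", "lfp.f32", "trials.csv", "licks.f32")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  ## and a second load reproduces the first exactly
  again <- loadSession(d2)
  expect_identical(lfpSamples(again$session), lfpSamples(loaded$session))
})

test_that("saving twice produces identical bytes", {
  sim <- toySession()
  d1 <- file.path(tempdir(), "det-a")
  d2 <- file.path(tempdir(), "det-b")
  saveSession(sim$session, sim$trials, d1)
  saveSession(sim$session, sim$trials, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "lfp.f32"))),
                   unname(tools::md5sum(file.path(d2, "lfp.f32"))))
  expect_identical(unname(tools::md5sum(file.path(d1, "trials.csv"))),
                   unname(tools::md5sum(file.path(d2, "trials.csv"))))
})

test_that("binary layout size is electrodes x samples x 4 bytes", {
  rate <- 500
  ses <- lfpSession(matrix(rnorm(2 * 10 * rate), nrow = 2), rate = rate,
                    sessionId = "toy2", subjectId = "m")
  tt <- trialTable(data.frame(trial_start_s = 1, odor_on_s = 2,
                              odorant = "S+", outcome = "Hit",
                              reinforced = TRUE))
  d <- file.path(tempdir(), "size-toy")
  saveSession(ses, tt, d)
  expect_equal(file.info(file.path(d, "lfp.f32"))$size, 2 * 10 * rate * 4)
})

test_that("metadata/sample-count mismatch and missing files are reported", {
  sim <- toySession()
  d <- file.path(tempdir(), "bad-ses")
  saveSession(sim$session, sim$trials, d)
  ## truncate the binary: declared electrode count no longer matches
  sz <- file.info(file.path(d, "lfp.f32"))$size
  con <- file(file.path(d, "lfp.f32"), "rb")
  raw <- readBin(con, "raw", n = sz - sz / 2)
  close(con)
  writeBin(raw, file.path(d, "lfp.f32"))
  expect_error(loadSession(d), "format error")

  expect_error(loadSession(file.path(tempdir(), "no-such-dir")),
               "metadata.json")
  file.remove(file.path(d, "trials.csv"))
  expect_error(loadSession(d), "trials.csv")
})

test_that("omitted outcome column is recomputed and flagged, matching hand-scored trials", {
  ## six hand-scored trials (odor at t = 10 s; response area 10.5-12.5 s)
  lick <- list(c(10.7, 11.2, 11.7, 12.2),      # S+ all four blocks -> Hit
               c(10.7, 11.2),                  # S+ first two only  -> Miss
               numeric(0),                     # S+ no licks        -> Miss
               c(10.6, 11.1, 11.6, 12.1),      # S- all four blocks -> FA
               c(10.2, 10.4),                  # S- pre-response    -> CR
               numeric(0))                     # S- silent          -> CR
  df <- data.frame(trial_start_s = rep(9, 6), odor_on_s = rep(10, 6),
                   odorant = c("S+", "S+", "S+", "S-", "S-", "S-"))
  df$lick_times <- lick
  tt <- trialTable(df)
  expect_equal(trialData(tt)$outcome,
               c("Hit", "Miss", "Miss", "FA", "CR", "CR"))
  expect_true(attr(trialData(tt), "derived_outcomes"))

  ## same table loaded from disk without an outcome column
  ses <- lfpSession(matrix(0.0 + rnorm(2 * 20 * 500), nrow = 2), rate = 500,
                    sessionId = "scored", subjectId = "m")
  d <- file.path(tempdir(), "derived-ses")
  dir.create(d, showWarnings = FALSE)
  saveSession(ses, tt, d)
  csv <- read.csv(file.path(d, "trials.csv"))
  csv$outcome <- NULL
  csv$reinforced <- NULL
  write.csv(csv, file.path(d, "trials.csv"), row.names = FALSE)
  loaded <- loadSession(d)
  expect_equal(trialData(loaded$trials)$outcome,
               c("Hit", "Miss", "Miss", "FA", "CR", "CR"))
})

test_that("unknown odorant labels are rejected on load", {
  sim <- toySession()
  d <- file.path(tempdir(), "odor-ses")
  saveSession(sim$session, sim$trials, d)
  csv <- read.csv(file.path(d, "trials.csv"))
  csv$odorant[1] <- "S?"
  write.csv(csv, file.path(d, "trials.csv"), row.names = FALSE)
  expect_error(loadSession(d), "unknown odorant")
})

test_that("class validity catches inconsistent objects", {
  expect_error(bandSpec("bad", 14, 6), "lowHz")
  expect_error(analysisConfig(nPhaseBins = 2), "nPhaseBins")
  expect_error(analysisConfig(odorWindowS = c(3, 9)), "odorWindowS")
  expect_error(lfpSession(matrix(c(1, NA), 1), rate = 100), "non-finite|NA")
  expect_error(lfpSession(matrix(1:10, 1), rate = -5), "rate")
  ## outcome inconsistent with odorant
  expect_error(trialTable(data.frame(trial_start_s = 0, odor_on_s = 1,
                                     odorant = "S+", outcome = "CR",
                                     reinforced = FALSE)),
               "inconsistent")
  expect_error(trialTable(data.frame(trial_start_s = 2, odor_on_s = 1,
                                     odorant = "S+", outcome = "Hit",
                                     reinforced = TRUE)),
               "odor_on_s")
})
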
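test_that("LOOCV LDA separates well-separated gaussian classes and is at chance on shuffled labels", {
  set.seed(2)
  n <- 20
  x <- rbind(matrix(rnorm(n * 4), n), matrix(rnorm(n * 4, mean = 6), n))
  labels <- rep(c("S+", "S-"), each = n)
  expect_gte(ldaLoocv(x, labels)$accuracy, 95)

  cloud <- matrix(rnorm(40 * 4), 40)
  rnd <- sample(rep(c("S+", "S-"), 20))
  acc <- ldaLoocv(cloud, rnd)$accuracy
  expect_gte(acc, 35)
  expect_lte(acc, 65)
})

test_that("1-D predictions match the closed-form two-class LDA boundary", {
  set.seed(4)
  x <- matrix(c(rnorm(12, 0, 1), rnorm(15, 3, 1)), ncol = 1)
  labels <- rep(c("a", "b"), c(12, 15))
  fit <- ldaLoocv(x, labels)
  ## independent closed form: pooled variance, midpoint + prior term
  for (i in seq_along(labels)) {
    xa <- x[-i, 1][labels[-i] == "a"]
    xb <- x[-i, 1][labels[-i] == "b"]
    s2 <- (sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) /
      (length(xa) + length(xb) - 2)
    s2 <- s2 + max(1e-6 * s2, 1e-12)
    score <- (mean(xa) - mean(xb)) / s2 *
      (x[i, 1] - (mean(xa) + mean(xb)) / 2) +
      log(length(xa) / length(xb))
    expect_equal(fit$predictions[i], if (score > 0) "a" else "b")
  }
})

test_that("LOOCV predictions agree with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(9)
  n <- 30
  x <- rbind(matrix(rnorm(n * 3, 0), n), matrix(rnorm(n * 3, 1.2), n))
  labels <- rep(c("S+", "S-"), each = n)
  ours <- ldaLoocv(x, labels)$predictions
  ref <- as.character(MASS::lda(x, grouping = labels, CV = TRUE)$class)
  expect_gte(mean(ours == ref), 0.97)
})

test_that("label swap flips every prediction (two-class symmetry)", {
  set.seed(11)
  x <- rbind(matrix(rnorm(24), 12), matrix(rnorm(24, 1), 12))
  labels <- rep(c("S+", "S-"), each = 12)
  swapped <- ifelse(labels == "S+", "S-", "S+")
  f1 <- ldaLoocv(x, labels)
  f2 <- ldaLoocv(x, swapped)
  ## training on swapped labels flips every prediction, so accuracy
  ## against the swapped labels is unchanged and accuracy of the flipped
  ## predictions against the ORIGINAL labels is the complement
  expect_equal(f2$predictions, ifelse(f1$predictions == "S+", "S-", "S+"))
  expect_equal(f2$accuracy, f1$accuracy)
  expect_equal(100 * mean(f2$predictions == labels), 100 - f1$accuracy)
})

test_that("ldaLoocv validates class structure", {
  x <- matrix(rnorm(20), 10)
  expect_error(ldaLoocv(x, rep("a", 10)), "two classes")
  expect_error(ldaLoocv(x, c(rep("a", 9), "b")), "at least 2 trials")
})

test_that("normalized AUC anchors and window invariance", {
  tb <- gridCentersForTest(c(-1.5, 4), 0.1)
  expect_equal(normalizedAuc(rep(50, length(tb)), tb), 0)
  expect_equal(normalizedAuc(rep(100, length(tb)), tb), 1)
  expect_equal(normalizedAuc(rep(75, length(tb)), tb), 0.5)
  ## accuracy outside the odor window is irrelevant
  acc <- rep(75, length(tb))
  acc2 <- acc
  acc2[tb < 0.5 | tb >= 2.5] <- runif(sum(tb < 0.5 | tb >= 2.5), 0, 100)
  expect_equal(normalizedAuc(acc2, tb), normalizedAuc(acc, tb))
  ## below-chance accuracy is clipped, not rewarded or penalized
  expect_equal(normalizedAuc(rep(30, length(tb)), tb), 0)
})

test_that("decoding a proficient session beats the shuffle band only after odor onset", {
  fx <- smallProficientChain()
  acc <- decodingAccuracy(fx$dec)
  pre <- acc$timebin_s < 0
  odor <- acc$timebin_s >= 0.5 & acc$timebin_s < 2.5
  expect_gte(mean(acc$accuracy[pre] <= acc$shuffled_hi[pre]), 0.8)
  expect_true(all(acc$accuracy[odor] > acc$shuffled_hi[odor]))
  expect_gt(fx$dec@auc, 0.8)
  ## shuffle control sits at chance
  expect_true(all(abs(acc$shuffled_mean - 50) < 15))
  ## correct outcomes decode well during odor
  expect_gt(mean(fx$dec@perOutcome[odor, "Hit"]), 90)
})

test_that("PC1 of a single-electrode tensor is the centered, sign-fixed PRP", {
  fx <- smallProficientChain()
  one <- fx$prp
  one@valuesDb <- one@valuesDb[, 1, , drop = FALSE]
  one@odorWindowMeanDb <- one@odorWindowMeanDb[, 1, drop = FALSE]
  one@referencePhases <- one@referencePhases[1, , drop = FALSE]
  pc1 <- pc1Timecourse(one, "proficient", fx$cfg)
  info <- trialData(one)
  keep <- info$stage == "proficient"
  j <- which(abs(timeBins(one) - 1.05) < 1e-9)
  v <- one@valuesDb[keep, 1, j]
  centered <- v - mean(v)
  got <- pc1$pc1_mean[pc1$timebin_s == timeBins(one)[j] &
                        pc1$odorant == "S+"]
  expectedUp <- mean(centered[info$odorant[keep] == "S+"])
  expect_equal(abs(got), abs(expectedUp), tolerance = 1e-6)
  ## sign fix: S+ odor-window mean non-negative
  ow <- pc1$odorant == "S+" & pc1$timebin_s >= 0.5 & pc1$timebin_s < 2.5
  expect_gte(mean(pc1$pc1_mean[ow]), 0)
})

test_that("PC1 group curves diverge only after odor onset", {
  fx <- smallProficientChain()
  pc1 <- fx$dec@pc1
  wide <- merge(pc1[pc1$odorant == "S+", c("timebin_s", "pc1_mean")],
                pc1[pc1$odorant == "S-", c("timebin_s", "pc1_mean")],
                by = "timebin_s", suffixes = c("_sp", "_sm"))
  gap <- abs(wide$pc1_mean_sp - wide$pc1_mean_sm)
  preLevel <- max(gap[wide$timebin_s < 0])
  odor <- wide$timebin_s >= 0.5 & wide$timebin_s < 2.5
  expect_true(all(gap[odor] > preLevel))
})
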
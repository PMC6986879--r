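#' Leave-one-out two-class linear discriminant analysis
#'
#' For each trial, a two-class LDA with pooled within-class covariance is
#' trained on all other trials and the held-out trial is classified. The
#' pooled covariance is regularized with a ridge of
#' \code{1e-6 * trace(S) / M} on the diagonal so that the discriminant is
#' defined even with more features than trials. Empirical class priors
#' are used. An exact tie in the discriminant score is broken by a seeded
#' coin flip.
#'
#' @param features trials x features numeric matrix.
#' @param labels per-trial class labels (exactly two classes, at least 2
#'   trials each).
#' @param seed seed for tie-breaking (default 1).
#' @return list with \code{predictions} (same type as labels),
#'   \code{accuracy} (percent correct) and \code{correct} (logical).
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 3), 20))
#' ldaLoocv(x, rep(c("a", "b"), each = 20))$accuracy
#' @export
ldaLoocv <- function(features, labels, seed = 1) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(labels) != n) stop("labels length must match rows of features")
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2) stop("exactly two classes are required")
  labels <- as.character(labels)
  if (min(table(labels)) < 2)
    stop("each class needs at least 2 trials")
  m <- ncol(features)
  i1 <- labels == classes[1]

  ## class sums and within-class scatter for downdating
  s1 <- colSums(features[i1, , drop = FALSE])
  s2 <- colSums(features[!i1, , drop = FALSE])
  n1 <- sum(i1); n2 <- n - n1
  mu1 <- s1 / n1; mu2 <- s2 / n2
  c1 <- sweep(features[i1, , drop = FALSE], 2, mu1)
  c2 <- sweep(features[!i1, , drop = FALSE], 2, mu2)
  sc <- crossprod(c1) + crossprod(c2)

  flips <- withLocalSeed(seed, stats::runif(n)) > 0.5
  pred <- character(n)
  for (i in seq_len(n)) {
    x <- features[i, ]
    if (i1[i]) {
      k1 <- n1 - 1; k2 <- n2
      m1 <- (s1 - x) / k1; m2 <- mu2
      ## remove sample i from the class-1 scatter
      d <- x - mu1
      sci <- sc - tcrossprod(d) * (n1 / k1)
    } else {
      k1 <- n1; k2 <- n2 - 1
      m1 <- mu1; m2 <- (s2 - x) / k2
      d <- x - mu2
      sci <- sc - tcrossprod(d) * (n2 / k2)
    }
    if (min(k1, k2) < 2) stop("each class needs at least 2 trials")
    S <- sci / (k1 + k2 - 2)
    eps <- 1e-6 * sum(diag(S)) / m
    diag(S) <- diag(S) + max(eps, 1e-12)
    w <- solve(S, m1 - m2)
    score <- sum(w * (x - (m1 + m2) / 2)) + log(k1 / k2)
    pred[i] <- if (score > 0) classes[1]
    else if (score < 0) classes[2]
    else classes[1 + flips[i]]
  }
  correct <- pred == labels
  list(predictions = pred, accuracy = 100 * mean(correct),
       correct = correct)
}

#' Normalized area under a decoding-accuracy time course
#'
#' Mean above-chance accuracy over the odor window, scaled so that
#' constant 50\% decoding maps to 0 and constant 100\% to 1. Accuracy
#' below chance is clipped at 0 before averaging.
#'
#' @param accuracy percent-correct per bin.
#' @param timebinsS bin centers (s).
#' @param odorWindow c(start, end) in seconds (default c(0.5, 2.5)).
#' @return normalized AUC in [0, 1].
#' @export
normalizedAuc <- function(accuracy, timebinsS, odorWindow = c(0.5, 2.5)) {
  sel <- timebinsS >= odorWindow[1] & timebinsS < odorWindow[2]
  mean(pmax(accuracy[sel] - 50, 0, na.rm = TRUE)) / 50
}

#' Per-time-bin LDA decoding of odorant identity from PRP
#'
#' Runs leave-one-out LDA on the per-electrode phase-referenced power at
#' every trial-aligned 0.1 s bin, together with a label-shuffle control
#' (the identical LOOCV on a permuted label vector -- a permutation
#' null), per-outcome accuracy of the held-out predictions, the PC1
#' group time courses, and the normalized AUC over the odor window.
#'
#' The shuffle band is the mean of the permutation accuracies with a 95\%
#' normal-theory prediction interval, i.e. the range in which a single
#' chance-level accuracy is expected to fall.
#'
#' @param prp a [PrpTensor-class].
#' @param stage analyse only trials of this stage ("proficient", "naive",
#'   or "all").
#' @param config an [AnalysisConfig-class]; \code{nShuffles} and
#'   \code{rngSeed} control the shuffle control.
#' @return a [DecodingTimecourse-class].
#' @export
decodeTimecourse <- function(prp, stage = "proficient",
                             config = analysisConfig()) {
  info <- prp@trialInfo
  keep <- !is.na(info$odorant)
  if (stage != "all" && !all(is.na(info$stage)))
    keep <- keep & info$stage == stage
  if (!is.null(info$outcome))
    keep <- keep & (is.na(info$outcome) | info$outcome != "undefined")
  vals <- prp@valuesDb[keep, , , drop = FALSE]
  info <- info[keep, , drop = FALSE]
  labels <- info$odorant
  if (length(unique(labels)) < 2 || min(table(labels)) < 2)
    stop("need at least 2 trials of each odorant in stage '", stage, "'")
  nb <- dim(vals)[3]
  nT <- dim(vals)[1]
  nsh <- config@nShuffles
  acc <- numeric(nb)
  shMean <- shLo <- shHi <- rep(NA_real_, nb)
  predSplus <- matrix(NA, nT, nb)
  outcomes <- c("Hit", "Miss", "CR", "FA")
  perOutcome <- matrix(NA_real_, nb, 4, dimnames = list(NULL, outcomes))

  shuffleSeeds <- vapply(seq_len(nsh), function(s)
    subSeed(config@rngSeed, s), numeric(1))
  perms <- withLocalSeed(subSeed(config@rngSeed, 0),
                         replicate(nsh, sample(nT), simplify = FALSE))

  for (j in seq_len(nb)) {
    X <- vals[, , j, drop = FALSE]
    dim(X) <- dim(vals)[1:2]
    fit <- ldaLoocv(X, labels, seed = subSeed(config@rngSeed, 1000 + j))
    acc[j] <- fit$accuracy
    predSplus[, j] <- fit$predictions == "S+"
    for (o in outcomes) {
      sel <- !is.na(info$outcome) & info$outcome == o
      if (any(sel)) perOutcome[j, o] <- 100 * mean(fit$correct[sel])
    }
    shAcc <- vapply(seq_len(nsh), function(s) {
      shuffledLoocvAccuracy(X, labels, perms[[s]], shuffleSeeds[s])
    }, numeric(1))
    shMean[j] <- mean(shAcc)
    spread <- stats::sd(shAcc) * sqrt(1 + 1 / nsh)
    q <- stats::qt(0.975, nsh - 1)
    shLo[j] <- shMean[j] - q * spread
    shHi[j] <- shMean[j] + q * spread
  }

  new("DecodingTimecourse", timebinsS = prp@timebinsS, accuracy = acc,
      shuffledMean = shMean, shuffledLo = shLo, shuffledHi = shHi,
      perOutcome = perOutcome,
      pc1 = pc1Timecourse(prp, stage = stage, config = config),
      auc = normalizedAuc(acc, prp@timebinsS, config@odorWindowS),
      predictedSplus = predSplus, trialInfo = info)
}

## permutation null: the identical LOOCV run on a permuted label vector,
## scored against the permuted labels. This inherits the leave-one-out
## class-imbalance anti-correlation (holding out a trial of one class
## leaves that class under-represented in training), so an
## informationless decoder is distributed exactly like the control;
## scoring shuffle-trained folds against the TRUE labels would lose that
## bias and sit above a null decoder.
shuffledLoocvAccuracy <- function(X, labels, perm, seed) {
  ldaLoocv(X, labels[perm], seed = seed)$accuracy
}

#' PC1 group time courses of phase-referenced power
#'
#' Per time bin, the principal axes of the trials x electrodes PRP matrix
#' are computed with both odorant classes pooled, and the mean PC1 score
#' is reported per odorant with a bootstrap 95\% CI. Axis orientation is
#' aligned across neighboring bins and the global sign is fixed so that
#' the S+ odor-window mean is non-negative.
#'
#' @param prp a [PrpTensor-class].
#' @param stage stage filter as in [decodeTimecourse()].
#' @param config an [AnalysisConfig-class].
#' @return data.frame: timebin_s, odorant, pc1_mean, pc1_lo, pc1_hi.
#' @export
pc1Timecourse <- function(prp, stage = "proficient",
                          config = analysisConfig()) {
  info <- prp@trialInfo
  keep <- !is.na(info$odorant)
  if (stage != "all" && !all(is.na(info$stage)))
    keep <- keep & info$stage == stage
  vals <- prp@valuesDb[keep, , , drop = FALSE]
  odorant <- info$odorant[keep]
  nb <- dim(vals)[3]
  scores <- matrix(0, dim(vals)[1], nb)
  prevAxis <- NULL
  for (j in seq_len(nb)) {
    X <- vals[, , j, drop = FALSE]
    dim(X) <- dim(vals)[1:2]
    Xc <- scale(X, scale = FALSE)
    if (max(abs(Xc)) < 1e-12) {
      warning("zero-variance bin ", j, ": PC1 set to 0")
      prevAxis <- NULL
      next
    }
    ax <- svd(Xc, nu = 0, nv = 1)$v[, 1]
    if (!is.null(prevAxis) && sum(ax * prevAxis) < 0) ax <- -ax
    prevAxis <- ax
    scores[, j] <- Xc %*% ax
  }
  ow <- config@odorWindowS
  sel <- prp@timebinsS >= ow[1] & prp@timebinsS < ow[2]
  if (mean(scores[odorant == "S+", sel]) < 0) scores <- -scores
  out <- lapply(c("S+", "S-"), function(o) {
    sub <- scores[odorant == o, , drop = FALSE]
    cis <- lapply(seq_len(nb), function(j)
      bootstrapCi(sub[, j], n = config@nBootstrap,
                  seed = subSeed(config@rngSeed, 2000 + j)))
    data.frame(timebin_s = prp@timebinsS, odorant = o,
               pc1_mean = colMeans(sub),
               pc1_lo = vapply(cis, function(ci) ci@lo, numeric(1)),
               pc1_hi = vapply(cis, function(ci) ci@hi, numeric(1)))
  })
  do.call(rbind, out)
}
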
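#' Two-sided Wilcoxon rank-sum p-value
#'
#' Midrank tie handling throughout. For small samples (both groups below
#' 10 observations) the p-value is computed by exhaustive enumeration of
#' all group assignments of the observed (mid)ranks; for larger samples
#' the tie-corrected normal approximation with continuity correction is
#' used. Degenerate inputs where every observation is tied give p = 1.
#'
#' @param x,y numeric samples (both nonempty).
#' @return two-sided p-value in (0, 1].
#' @examples
#' ranksumPvalue(c(1, 2, 3), c(10, 11, 12))  # 0.1, the exact 3-vs-3 extreme
#' @export
ranksumPvalue <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be nonempty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  nt <- n1 + n2
  if (max(table(r)) == nt) return(1)   # everything tied
  if (n1 < 10 && n2 < 10) {
    ## exact: enumerate all assignments of the midranks to group 1
    combs <- utils::combn(nt, n1)
    ws <- colSums(matrix(r[combs], nrow = n1))
    eps <- 1e-9
    pLo <- mean(ws <= w + eps)
    pHi <- mean(ws >= w - eps)
    return(min(1, 2 * min(pLo, pHi)))
  }
  mu <- n1 * (nt + 1) / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
  if (sig2 <= 0) return(1)
  z <- (abs(w - mu) - 0.5) / sqrt(sig2)
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

#' Decision time from a p-value time course
#'
#' The decision time is the earliest bin at or after \code{tStart} whose
#' p-value is below \code{alpha} and stays below \code{alpha} for every
#' subsequent bin through \code{tEnd} (the end of odor delivery).
#' Transient dips that recover do not count.
#'
#' @param p p-value per bin (NA bins are treated as not significant).
#' @param timebinsS bin centers (s), or a [PValueSeries-class] as first
#'   argument with \code{timebinsS} omitted.
#' @param alpha significance level (default 0.05).
#' @param tStart,tEnd window over which the crossing must be sustained
#'   (defaults 0 and 2.5 s).
#' @return decision time in seconds, or NA if no sustained crossing.
#' @export
decisionTime <- function(p, timebinsS = NULL, alpha = 0.05, tStart = 0,
                         tEnd = 2.5) {
  if (is(p, "PValueSeries")) {
    timebinsS <- p@timebinsS
    p <- p@p
  }
  sel <- which(timebinsS >= tStart & timebinsS <= tEnd)
  if (!length(sel)) return(NA_real_)
  sig <- !is.na(p[sel]) & p[sel] < alpha
  if (!sig[length(sig)]) return(NA_real_)
  lastBad <- max(c(0L, which(!sig)))
  if (lastBad == length(sig)) return(NA_real_)
  timebinsS[sel[lastBad + 1L]]
}

## build a PValueSeries from a trials x bins score matrix and group labels
scoreSeries <- function(scores, splus, timebinsS, source, alpha = 0.05,
                        tEnd = 2.5) {
  p <- vapply(seq_len(ncol(scores)), function(j) {
    ranksumPvalue(scores[splus, j], scores[!splus, j])
  }, numeric(1))
  new("PValueSeries", timebinsS = timebinsS, p = p, source = source,
      decisionTimeS = decisionTime(p, timebinsS, alpha = alpha,
                                   tEnd = tEnd))
}

#' Lick and decoder decision times over pooled sessions
#'
#' Builds the S+ vs S- rank-sum p-value time course for (i) binarized
#' licks and (ii) the per-trial LDA prediction of odorant identity
#' (held-out prediction scored 1 when the decoder calls the trial S+),
#' and extracts the sustained sub-alpha decision time of each. Trials
#' from all supplied sessions are pooled.
#'
#' The decoder series uses the predicted contextual identity rather than
#' a correct/incorrect score: prediction-vs-truth agreement is identical
#' between the two groups whenever the decoder is symmetric, so only the
#' predicted identity can diverge between S+ and S- trials.
#'
#' @param trialTables list of [TrialTable-class] (or a single one).
#' @param decodings list of [DecodingTimecourse-class] matching the trial
#'   tables (e.g. from [decodeTimecourse()] with peak- or
#'   trough-referenced PRP), or NULL for licks only.
#' @param config an [AnalysisConfig-class].
#' @param decoderSource tag for the decoder series (default "lda_peak").
#' @return named list of [PValueSeries-class]: \code{licks} and, when
#'   decodings are given, one entry named by \code{decoderSource}.
#' @export
lickDecoderDecisionTimes <- function(trialTables, decodings = NULL,
                                     config = analysisConfig(),
                                     decoderSource = "lda_peak") {
  if (is(trialTables, "TrialTable")) trialTables <- list(trialTables)
  if (is(decodings, "DecodingTimecourse")) decodings <- list(decodings)
  alpha <- config@alpha
  tEnd <- config@odorWindowS[2]
  out <- list()

  lickMats <- list(); lickSplus <- list()
  for (k in seq_along(trialTables)) {
    bt <- behaviorTimecourse(trialTables[[k]], config)
    tr <- trialTables[[k]]@trials
    keep <- tr$outcome != "undefined"
    lickMats[[k]] <- bt$lickMatrix[keep, , drop = FALSE]
    lickSplus[[k]] <- tr$odorant[keep] == "S+"
    timebinsS <- bt$timebinsS
  }
  out$licks <- scoreSeries(do.call(rbind, lickMats), unlist(lickSplus),
                           timebinsS, "licks", alpha, tEnd)

  if (!is.null(decodings)) {
    predMats <- lapply(decodings, function(d) d@predictedSplus * 1)
    splus <- unlist(lapply(decodings, function(d)
      d@trialInfo$odorant == "S+"))
    out[[decoderSource]] <- scoreSeries(do.call(rbind, predMats), splus,
                                        decodings[[1]]@timebinsS,
                                        decoderSource, alpha, tEnd)
  }
  out
}
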
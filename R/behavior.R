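#' Score a go/no-go trial outcome from its licks
#'
#' A trial is scored as a "go" response when the animal licks at least
#' once in each of four consecutive 0.5 s blocks of the response area
#' (default: odor-aligned 0.5--2.5 s). For the rewarded odorant (S+) a go
#' is a Hit and anything else a Miss; for the unrewarded odorant (S-) a
#' go is a False Alarm and anything else a Correct Rejection.
#'
#' @param odorant "S+" or "S-".
#' @param lickTimesS lick times in seconds, trial-aligned (odor onset = 0).
#' @param responseStartS onset of the first response block (default 0.5).
#' @param blockS block duration (default 0.5); \code{nBlocks} blocks.
#' @param nBlocks number of blocks (default 4).
#' @return one of "Hit", "Miss", "CR", "FA".
#' @examples
#' classifyOutcome("S+", c(0.7, 1.2, 1.7, 2.2))  # "Hit"
#' @export
classifyOutcome <- function(odorant, lickTimesS, responseStartS = 0.5,
                            blockS = 0.5, nBlocks = 4) {
  if (length(odorant) != 1 || !odorant %in% c("S+", "S-"))
    stop("odorant must be 'S+' or 'S-'")
  starts <- responseStartS + (seq_len(nBlocks) - 1) * blockS
  go <- all(vapply(starts, function(s)
    any(lickTimesS >= s & lickTimesS < s + blockS), logical(1)))
  if (odorant == "S+") {
    if (go) "Hit" else "Miss"
  } else {
    if (go) "FA" else "CR"
  }
}

#' Sliding-window percent correct
#'
#' Percent of correct responses (Hit or CR) in a trailing window of
#' \code{window} trials, stepped one trial at a time. Trials before the
#' first full window take the first full-window value. If fewer trials
#' than \code{window} exist, every trial takes the percent correct of the
#' full set and the result carries attribute \code{partial_window = TRUE}.
#'
#' @param outcomes character vector of per-trial outcomes, in trial order.
#' @param window window length in trials (default 20).
#' @return numeric vector of per-trial percent correct in [0, 100].
#' @export
slidingPerformance <- function(outcomes, window = 20) {
  n <- length(outcomes)
  correct <- as.numeric(outcomes %in% c("Hit", "CR"))
  if (n == 0) return(numeric(0))
  if (n < window) {
    pc <- rep(100 * mean(correct), n)
    attr(pc, "partial_window") <- TRUE
    return(pc)
  }
  cs <- cumsum(correct)
  full <- (cs[window:n] - c(0, cs[seq_len(n - window)])) / window * 100
  c(rep(full[1], window - 1), full)
}

#' Segment trials into learning stages by sliding performance
#'
#' Performance at or below 65\% correct is naive, at or above 80\% is
#' proficient (both inclusive); the 65--80\% window is labeled
#' intermediate and excluded from group analyses downstream.
#'
#' @param percentCorrect per-trial sliding performance (\%).
#' @return character vector: "naive", "intermediate" or "proficient".
#' @export
segmentStages <- function(percentCorrect) {
  ifelse(percentCorrect <= 65, "naive",
         ifelse(percentCorrect >= 80, "proficient", "intermediate"))
}

#' Binarize lick times onto a time grid
#'
#' A bin is 1 if at least one lick falls in it (licks are scored 0/1 per
#' bin, not counted).
#'
#' @param lickTimesS lick times (s), in the same time base as the grid.
#' @param gridEdges bin edges (length nBins + 1, increasing).
#' @return integer vector of 0/1 of length \code{length(gridEdges) - 1}.
#' @export
lickBinarize <- function(lickTimesS, gridEdges) {
  nb <- length(gridEdges) - 1
  if (nb < 1) stop("grid must have at least one bin")
  if (!length(lickTimesS)) return(integer(nb))
  idx <- findInterval(lickTimesS, gridEdges)
  idx <- idx[idx >= 1 & idx <= nb &
               lickTimesS < gridEdges[nb + 1]]
  out <- integer(nb)
  out[unique(idx)] <- 1L
  out
}

#' Behavioral time course for a session
#'
#' Bundles per-trial sliding performance, stage labels, and the
#' trials x time-bins binary lick matrix on the trial-aligned grid.
#'
#' @param trialTable a [TrialTable-class].
#' @param config an [AnalysisConfig-class].
#' @return list with \code{percentCorrect}, \code{stage},
#'   \code{lickMatrix} (trials x bins, 0/1) and \code{timebinsS}.
#' @export
behaviorTimecourse <- function(trialTable, config = analysisConfig()) {
  tr <- trialTable@trials
  edges <- seq(config@trialWindowS[1], config@trialWindowS[2],
               by = config@timebinS)
  lickMatrix <- t(vapply(seq_len(nrow(tr)), function(i)
    lickBinarize(tr$lick_times[[i]] - tr$odor_on_s[i], edges),
    integer(length(edges) - 1)))
  list(percentCorrect = trialTable@percentCorrect, stage = trialTable@stage,
       lickMatrix = lickMatrix,
       timebinsS = gridCenters(config@trialWindowS, config@timebinS))
}
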
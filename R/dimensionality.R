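#' Participation-ratio dimensionality of an eigenvalue spectrum
#'
#' \eqn{dim = (\sum_i \lambda_i)^2 / \sum_i \lambda_i^2} for the
#' eigenvalues of a covariance matrix. Equals the number of channels M
#' when all eigenvalues are equal, and m when exactly m eigenvalues are
#' equal and the rest are zero. Small negative eigenvalues from finite-
#' precision symmetric decompositions are floored at zero.
#'
#' @param lambdas eigenvalues (at least one strictly positive).
#' @return participation ratio in [1, length(lambdas)].
#' @examples
#' participationRatio(rep(2, 16))  # 16
#' participationRatio(c(3, 1))    # 1.6
#' @export
participationRatio <- function(lambdas) {
  if (any(lambdas < -1e-9 * max(abs(lambdas), 1)))
    stop("spectrum has a substantially negative eigenvalue; ",
         "not a covariance spectrum")
  l <- pmax(lambdas, 0)
  if (sum(l) <= 0)
    stop("all-zero spectrum: dimensionality undefined")
  sum(l)^2 / sum(l^2)
}

## participation ratio of the covariance of an n x M data matrix
dataDim <- function(X) {
  if (nrow(X) < 2) return(NA_real_)
  C <- stats::cov(X)
  participationRatio(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
}

#' Participation-ratio dimensionality time course
#'
#' Per trial-aligned 0.1 s bin, the covariance across trials of the
#' M-channel PRP vectors is formed and its participation ratio computed,
#' separately per (odorant x stage) group by default (set
#' \code{groupByOdorant = FALSE} to pool both odorants). Curves are
#' additionally reported normalized to the mean dimensionality over the
#' pre-trial baseline window.
#'
#' @param prp a [PrpTensor-class] (single session or pooled).
#' @param stage stage filter ("proficient", "naive" or "all").
#' @param groupByOdorant compute per odorant (default) or pooled.
#' @param config an [AnalysisConfig-class]; \code{baselineWindowS} sets
#'   the normalization window.
#' @return a [DimTimecourse-class].
#' @export
dimTimecourse <- function(prp, stage = "proficient", groupByOdorant = TRUE,
                          config = analysisConfig()) {
  info <- prp@trialInfo
  keep <- !is.na(info$odorant)
  if (stage != "all" && !all(is.na(info$stage)))
    keep <- keep & info$stage == stage
  vals <- prp@valuesDb[keep, , , drop = FALSE]
  odorant <- info$odorant[keep]
  M <- dim(vals)[2]
  groups <- if (groupByOdorant) unique(odorant) else "pooled"
  nb <- dim(vals)[3]
  bw <- config@baselineWindowS
  base <- prp@timebinsS >= bw[1] & prp@timebinsS < bw[2]
  curves <- lapply(groups, function(g) {
    sel <- if (groupByOdorant) odorant == g else rep(TRUE, length(odorant))
    if (sum(sel) < M + 2)
      warning("group ", g, ": fewer than M+2 trials (", sum(sel),
              "); dimensionality estimates will be noisy")
    d <- vapply(seq_len(nb), function(j) {
      X <- vals[sel, , j, drop = FALSE]
      dim(X) <- c(sum(sel), M)
      dataDim(X)
    }, numeric(1))
    b <- mean(d[base], na.rm = TRUE)
    data.frame(group = g, timebin_s = prp@timebinsS, dim = d,
               normalized_dim = d / b)
  })
  new("DimTimecourse", timebinsS = prp@timebinsS,
      curves = do.call(rbind, curves), nChannels = M)
}

#' Pool PRP tensors across sessions (mice)
#'
#' Concatenates the electrode dimension across sessions. Per odorant, the
#' pooled trial count is the minimum trial count across sessions (the
#' first n trials of each session, in session order), so every pooled
#' pseudo-trial has a value on every channel. Stage labels are taken from
#' the first session's retained trials; outcomes are dropped (set NA)
#' since they are not aligned across animals.
#'
#' @param prps list of [PrpTensor-class] with identical time grids,
#'   references and bands.
#' @return a pooled [PrpTensor-class] with \code{16 x N}-style channel
#'   count.
#' @export
poolSessions <- function(prps) {
  if (is(prps, "PrpTensor")) return(prps)
  if (!length(prps)) stop("no sessions to pool")
  if (length(prps) == 1) return(prps[[1]])
  tb <- prps[[1]]@timebinsS
  for (p in prps) {
    if (length(p@timebinsS) != length(tb) ||
        max(abs(p@timebinsS - tb)) > 1e-9)
      stop("sessions have different time grids")
    if (p@reference != prps[[1]]@reference)
      stop("sessions have different reference phases")
  }
  counts <- sapply(c("S+", "S-"), function(o)
    min(vapply(prps, function(p) sum(p@trialInfo$odorant == o), numeric(1))))
  if (any(counts == 0))
    stop("an odorant has zero overlapping trials across sessions")
  pieces <- lapply(prps, function(p) {
    idx <- unlist(lapply(c("S+", "S-"), function(o)
      which(p@trialInfo$odorant == o)[seq_len(counts[[o]])]))
    list(vals = p@valuesDb[idx, , , drop = FALSE],
         ow = p@odorWindowMeanDb[idx, , drop = FALSE],
         info = p@trialInfo[idx, , drop = FALSE])
  })
  vals <- do.call(abind3, lapply(pieces, `[[`, "vals"))
  ow <- do.call(cbind, lapply(pieces, `[[`, "ow"))
  info <- pieces[[1]]$info
  info$outcome <- NA_character_
  refs <- do.call(rbind, lapply(seq_along(prps), function(k) {
    r <- prps[[k]]@referencePhases
    r$session <- k
    r
  }))
  new("PrpTensor", valuesDb = vals, reference = prps[[1]]@reference,
      band = prps[[1]]@band, timebinsS = tb, odorWindowMeanDb = ow,
      trialInfo = info, referencePhases = refs)
}

## bind 3-d arrays along dimension 2 (channels)
abind3 <- function(...) {
  args <- list(...)
  d <- dim(args[[1]])
  out <- array(NA_real_, c(d[1], sum(vapply(args, function(a) dim(a)[2],
                                            numeric(1))), d[3]))
  at <- 0
  for (a in args) {
    out[, at + seq_len(dim(a)[2]), ] <- a
    at <- at + dim(a)[2]
  }
  out
}
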
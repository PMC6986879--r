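## unwrap a phase series given in degrees
unwrapDeg <- function(p) {
  d <- diff(p)
  d <- d - 360 * round(d / 360)
  cumsum(c(p[1], d))
}

#' Times at which the carrier phase crosses a reference phase
#'
#' Returns one time per completed carrier cycle: the (linearly
#' interpolated) instant at which the unwrapped phase passes
#' \code{referenceDeg} in the increasing direction.
#'
#' @param phaseDeg carrier phase series in degrees.
#' @param referenceDeg reference phase in degrees.
#' @param rate sampling rate (Hz).
#' @return numeric vector of crossing times (s, relative to the first
#'   sample); possibly empty for very short inputs.
#' @export
referenceCrossingTimes <- function(phaseDeg, referenceDeg, rate) {
  u <- unwrapDeg(phaseDeg)
  k <- floor((u - referenceDeg) / 360)
  hit <- which(diff(k) >= 1)
  if (!length(hit)) return(numeric(0))
  out <- numeric(0)
  for (i in hit) {
    for (m in (k[i] + 1):k[i + 1]) {
      target <- 360 * m + referenceDeg
      frac <- (target - u[i]) / (u[i + 1] - u[i])
      out <- c(out, (i - 1 + frac) / rate)
    }
  }
  out
}

## sample a per-sample series at crossing times and average into the
## trial-aligned grid; empty bins linearly interpolated, edges carried.
binCrossingValues <- function(valueSeries, crossTimes, rate, odorOnS,
                              window, dt) {
  edges <- seq(window[1], window[2], by = dt)
  nb <- length(edges) - 1
  rel <- crossTimes - odorOnS
  sel <- rel >= window[1] & rel < window[2]
  rel <- rel[sel]
  idx <- round((crossTimes[sel]) * rate) + 1
  idx <- pmin(pmax(idx, 1), length(valueSeries))
  v <- valueSeries[idx]
  bin <- findInterval(rel, edges, rightmost.closed = FALSE)
  out <- rep(NA_real_, nb)
  if (length(v)) {
    agg <- rowsum(v, bin)
    cnt <- tabulate(bin, nb)
    out[as.integer(rownames(agg))] <- agg / cnt[as.integer(rownames(agg))]
  }
  fillGapsLinear(out)
}

#' Phase-referenced power for one trial and electrode
#'
#' Convenience single-trial wrapper around the session-level machinery:
#' filters the electrode's trace, finds the crossings of the requested
#' reference phase, samples the instantaneous Morlet band power at each
#' crossing, and averages into the trial-aligned 0.1 s grid (empty bins
#' linearly interpolated).
#'
#' @param session an [LfpSession-class].
#' @param trialTable a [TrialTable-class].
#' @param trial trial index.
#' @param electrode electrode index.
#' @param band fast band.
#' @param referencePhaseDeg reference phase (deg), normally the
#'   electrode's S+ PAC peak or trough phase.
#' @param config an [AnalysisConfig-class].
#' @return numeric vector of PRP (dB) on the trial-aligned grid.
#' @export
trialPrp <- function(session, trialTable, trial, electrode, band,
                     referencePhaseDeg, config = analysisConfig()) {
  rate <- session@rate
  x <- session@samples[electrode, ]
  lo <- bandpassFilter(x, config@bands$theta, rate, config@filterOrder)
  phase <- wrap360(Arg(analyticSignal(lo)) * 180 / pi)
  power <- morletBandPower(x, rate, as_band(band), config@waveletCycles)
  ct <- referenceCrossingTimes(phase, referencePhaseDeg, rate)
  odorOn <- trialTable@trials$odor_on_s[trial]
  if (odorOn + config@trialWindowS[2] > ncol(session@samples) / rate)
    warning("trial ", trial, " shorter than the analysis grid; ",
            "trailing bins are extrapolated")
  binCrossingValues(power, ct, rate, odorOn, config@trialWindowS,
                    config@timebinS)
}

#' Phase-referenced power tensor for a whole session
#'
#' For every electrode, extracts the theta phase and the Morlet band
#' power of the fast band over the continuous recording, samples the
#' power at each crossing of the electrode's reference phase (peak or
#' trough of the S+ PAC distribution), and averages the samples into the
#' trial-aligned 0.1 s grid for every trial. Trials with undefined
#' outcome are excluded.
#'
#' @param session an [LfpSession-class].
#' @param trialTable a [TrialTable-class].
#' @param band fast band (default "high_gamma").
#' @param reference "peak" or "trough".
#' @param config an [AnalysisConfig-class].
#' @param pac optional precomputed result of [sessionPac()] for this
#'   session and band (avoids recomputation when both references are
#'   needed).
#' @return a [PrpTensor-class].
#' @export
sessionPrp <- function(session, trialTable, band = "high_gamma",
                       reference = c("peak", "trough"),
                       config = analysisConfig(), pac = NULL) {
  reference <- match.arg(reference)
  band <- as_band(band)
  if (is.null(pac))
    pac <- sessionPac(session, trialTable, config@bands$theta, band, config)
  refPhases <- pac$reference[[if (reference == "peak") "peak_deg"
                              else "trough_deg"]]
  rate <- session@rate
  tr <- trialTable@trials
  stage <- trialTable@stage
  keep <- which(tr$outcome != "undefined")
  nT <- length(keep)
  nEl <- nrow(session@samples)
  grid <- gridCenters(config@trialWindowS, config@timebinS)
  nb <- length(grid)
  vals <- array(NA_real_, c(nT, nEl, nb))
  for (el in seq_len(nEl)) {
    x <- session@samples[el, ]
    lo <- bandpassFilter(x, config@bands$theta, rate, config@filterOrder)
    phase <- wrap360(Arg(analyticSignal(lo)) * 180 / pi)
    power <- morletBandPower(x, rate, band, config@waveletCycles)
    ct <- referenceCrossingTimes(phase, refPhases[el], rate)
    for (i in seq_len(nT)) {
      vals[i, el, ] <- binCrossingValues(power, ct, rate,
                                         tr$odor_on_s[keep[i]],
                                         config@trialWindowS,
                                         config@timebinS)
    }
  }
  ow <- config@odorWindowS
  sel <- grid >= ow[1] & grid < ow[2]
  owMean <- apply(vals[, , sel, drop = FALSE], c(1, 2), mean)
  info <- data.frame(odorant = tr$odorant[keep], stage = stage[keep],
                     outcome = tr$outcome[keep])
  new("PrpTensor", valuesDb = vals, reference = reference, band = band,
      timebinsS = grid, odorWindowMeanDb = owMean, trialInfo = info,
      referencePhases = data.frame(electrode = seq_len(nEl),
                                   phase_deg = refPhases))
}

#' Group means of odor-window PRP with bootstrap confidence intervals
#'
#' Per electrode and (odorant x stage) group, the mean phase-referenced
#' power over the odor window with a 95\% percentile-bootstrap CI.
#' Groups with fewer than 2 trials are omitted with a warning.
#'
#' @param prps a [PrpTensor-class] or a (possibly named) list of them
#'   (e.g. peak- and trough-referenced).
#' @param config an [AnalysisConfig-class].
#' @return data.frame: reference, band, electrode, odorant, stage,
#'   n_trials, mean_db, lo_db, hi_db.
#' @export
prpSummary <- function(prps, config = analysisConfig()) {
  if (is(prps, "PrpTensor")) prps <- list(prps)
  rows <- list()
  for (prp in prps) {
    info <- prp@trialInfo
    groups <- unique(info[info$stage != "intermediate" &
                            info$outcome != "undefined",
                          c("odorant", "stage")])
    for (gi in seq_len(nrow(groups))) {
      sel <- which(info$odorant == groups$odorant[gi] &
                     info$stage == groups$stage[gi])
      if (length(sel) < 2) {
        warning("group ", groups$odorant[gi], "/", groups$stage[gi],
                " has fewer than 2 trials; omitted")
        next
      }
      for (el in seq_len(ncol(prp@odorWindowMeanDb))) {
        ci <- bootstrapCi(prp@odorWindowMeanDb[sel, el],
                          n = config@nBootstrap,
                          seed = subSeed(config@rngSeed, 3000 + 100 * gi + el))
        rows[[length(rows) + 1]] <-
          data.frame(reference = prp@reference, band = prp@band@name,
                     electrode = el, odorant = groups$odorant[gi],
                     stage = groups$stage[gi], n_trials = length(sel),
                     mean_db = ci@point, lo_db = ci@lo, hi_db = ci@hi)
      }
    }
  }
  do.call(rbind, rows)
}
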
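#' Amplitude-by-phase distribution, modulation index and peak/trough phases
#'
#' Bins the fast-band amplitude envelope by carrier phase (51 bins by
#' default), normalizes the per-bin mean amplitudes to a probability
#' distribution, and quantifies its distance from uniform with the
#' Kullback-Leibler modulation index.
#'
#' @param phaseDeg carrier phase series in degrees (any real values;
#'   wrapped to [0, 360)).
#' @param envelope fast-band amplitude envelope, same length.
#' @param nBins number of phase bins (default 51).
#' @return a [PacDistribution-class] object.
#' @examples
#' ph <- seq(0, 360 * 20, length.out = 5000) %% 360
#' d <- pacDistribution(ph, 1 + 0.3 * cos((ph - 180) * pi / 180))
#' modulationIndex(d@p)
#' @export
pacDistribution <- function(phaseDeg, envelope, nBins = 51) {
  if (length(phaseDeg) != length(envelope))
    stop("phase and envelope must have the same length")
  if (nBins < 3) stop("nBins must be >= 3")
  if (any(envelope < 0)) stop("envelope must be nonnegative")
  width <- 360 / nBins
  bin <- pmin(floor((phaseDeg %% 360) / width) + 1L, nBins)
  cnt <- tabulate(bin, nbins = nBins)
  if (any(cnt == 0))
    stop("phase bin(s) with zero samples: provide a longer input so every ",
         "bin is populated")
  means <- as.numeric(rowsum(envelope, bin)) / cnt
  p <- means / sum(means)
  centers <- (seq_len(nBins) - 0.5) * width
  h <- shannonEntropy(p)
  new("PacDistribution", binCentersDeg = centers, p = p,
      mi = (log(nBins) - h) / log(nBins), entropy = h,
      peakPhaseDeg = centers[which.max(p)],
      troughPhaseDeg = centers[which.min(p)])
}

shannonEntropy <- function(p) {
  nz <- p[p > 0]
  -sum(nz * log(nz))
}

#' Kullback-Leibler modulation index of a phase distribution
#'
#' \eqn{MI = (\ln N - H)/\ln N} where \eqn{H} is the Shannon entropy of
#' the normalized amplitude-by-phase distribution \code{p}. MI is 0 for a
#' uniform distribution (no coupling) and 1 for a delta distribution
#' (all amplitude at one phase bin).
#'
#' @param p normalized, nonnegative distribution over phase bins.
#' @return modulation index in [0, 1].
#' @export
modulationIndex <- function(p) {
  if (any(p < 0)) stop("p must be nonnegative")
  if (abs(sum(p) - 1) > 1e-6)
    stop("p is not normalized: sum(p) = ", format(sum(p)))
  n <- length(p)
  (log(n) - shannonEntropy(p)) / log(n)
}

#' Circular variance of per-trial peak angles
#'
#' Returns \eqn{1 - R} where \eqn{R} is the mean resultant length of the
#' angles, a number in [0, 1]: 0 when all trials share one peak phase,
#' approaching 1 when peak phases are uniformly dispersed. The alternative
#' \code{method = "linear_deg2"} reports the variance (deg^2) of the
#' angles after unwrapping about their circular mean.
#'
#' @param anglesDeg per-trial peak phases in degrees (at least 2).
#' @param method "circular" (default) or "linear_deg2".
#' @return circular variance in [0, 1], or a deg^2 variance.
#' @export
peakAngleVariance <- function(anglesDeg, method = c("circular", "linear_deg2")) {
  method <- match.arg(method)
  if (length(anglesDeg) < 2)
    stop("need at least 2 angles")
  z <- exp(1i * anglesDeg * pi / 180)
  if (method == "circular") return(1 - Mod(mean(z)))
  mu <- Arg(mean(z)) * 180 / pi
  dev <- ((anglesDeg - mu + 180) %% 360) - 180
  stats::var(dev)
}

circularMeanDeg <- function(anglesDeg) {
  (Arg(mean(exp(1i * anglesDeg * pi / 180))) * 180 / pi) %% 360
}

#' Run the full PAC chain on a raw signal
#'
#' Band-pass filters the signal into a carrier and a fast band (zero-phase
#' Butterworth), extracts Hilbert phase and envelope, and bins the
#' envelope by phase. This is the complete modulation-index measurement
#' applied to one continuous signal, used both on trial windows and on
#' standalone simulation signals.
#'
#' @param x raw signal.
#' @param rate sampling rate (Hz).
#' @param lowBand,highBand carrier and fast bands ([BandSpec-class],
#'   numeric pair, or default band name).
#' @param nBins phase bins (default 51).
#' @param filterOrder Butterworth prototype order (default 20).
#' @return a [PacDistribution-class].
#' @examples
#' sig <- simulatePacSignal(simulationConfig(coupling = "burst",
#'                                           durationS = 4, rate = 2000))
#' pacChain(sig$signal, 2000, "theta", "low_gamma_sim")@mi
#' @export
pacChain <- function(x, rate, lowBand = "theta", highBand = "high_gamma",
                     nBins = 51, filterOrder = 20) {
  lo <- bandpassFilter(x, as_band(lowBand), rate, filterOrder)
  hi <- bandpassFilter(x, as_band(highBand), rate, filterOrder)
  pe <- phaseEnvelope(lo, hi)
  pacDistribution(pe$phaseDeg, pe$envelope, nBins)
}

#' Per-trial and per-group PAC for a session
#'
#' Filters every electrode of the session into the carrier and fast bands,
#' computes the per-trial amplitude-by-phase distribution over the
#' trial-aligned PAC window (default 0--2.5 s after odor onset), and
#' summarizes by (odorant x stage) group. The session reference peak and
#' trough phases -- later used to sample phase-referenced power -- are
#' computed per electrode from the pooled S+ trials only, following the
#' convention that reference phases are defined on rewarded-odorant trials.
#'
#' Trials with undefined outcome and trials in the intermediate
#' performance stage are excluded from group summaries (but intermediate
#' trials are retained in the per-trial table).
#'
#' @param session an [LfpSession-class].
#' @param trialTable a [TrialTable-class].
#' @param lowBand,highBand carrier and fast bands.
#' @param config an [AnalysisConfig-class].
#' @return list with elements
#'   \describe{
#'     \item{trials}{data.frame: trial, electrode, odorant, stage, mi,
#'       peak_deg, trough_deg (one row per trial x electrode).}
#'     \item{reference}{data.frame: electrode, peak_deg, trough_deg from
#'       pooled S+ trials.}
#'     \item{groups}{data.frame: odorant, stage, n_trials, mean_mi,
#'       peak_deg, trough_deg, peak_angle_variance.}
#'     \item{groupDistributions}{named list of [PacDistribution-class],
#'       one per group, averaged over trials and electrodes.}
#'   }
#' @export
sessionPac <- function(session, trialTable, lowBand = "theta",
                       highBand = "high_gamma", config = analysisConfig()) {
  lowBand <- as_band(lowBand)
  highBand <- as_band(highBand)
  tr <- trialTable@trials
  stage <- trialTable@stage
  keep <- tr$outcome != "undefined"
  if (!any(tr$odorant[keep] == "S+"))
    stop("no S+ trials: session reference phases are undefined")
  rate <- session@rate
  nEl <- nrow(session@samples)
  nBins <- config@nPhaseBins
  win <- config@pacWindowS
  nT <- nrow(tr)

  idxOf <- function(i) {
    i0 <- floor((tr$odor_on_s[i] + win[1]) * rate) + 1L
    i1 <- floor((tr$odor_on_s[i] + win[2]) * rate)
    i0:min(i1, ncol(session@samples))
  }
  trialIdx <- lapply(seq_len(nT), idxOf)
  splusIdx <- unlist(trialIdx[keep & tr$odorant == "S+"])

  rows <- vector("list", nEl)
  refRows <- vector("list", nEl)
  pSums <- list()   # group -> running sum of per-trial p vectors
  pN <- list()

  for (el in seq_len(nEl)) {
    lo <- bandpassFilter(session@samples[el, ], lowBand, rate,
                         config@filterOrder)
    hi <- bandpassFilter(session@samples[el, ], highBand, rate,
                         config@filterOrder)
    pe <- phaseEnvelope(lo, hi)
    mi <- peak <- trough <- rep(NA_real_, nT)
    for (i in seq_len(nT)) {
      if (!keep[i]) next
      d <- pacDistribution(pe$phaseDeg[trialIdx[[i]]],
                           pe$envelope[trialIdx[[i]]], nBins)
      mi[i] <- d@mi
      peak[i] <- d@peakPhaseDeg
      trough[i] <- d@troughPhaseDeg
      if (stage[i] != "intermediate") {
        g <- paste(tr$odorant[i], stage[i], sep = ".")
        if (is.null(pSums[[g]])) { pSums[[g]] <- 0; pN[[g]] <- 0 }
        pSums[[g]] <- pSums[[g]] + d@p
        pN[[g]] <- pN[[g]] + 1
      }
    }
    rows[[el]] <- data.frame(trial = seq_len(nT), electrode = el,
                             odorant = tr$odorant, stage = stage,
                             mi = mi, peak_deg = peak, trough_deg = trough)
    dref <- pacDistribution(pe$phaseDeg[splusIdx], pe$envelope[splusIdx],
                            nBins)
    refRows[[el]] <- data.frame(electrode = el,
                                peak_deg = dref@peakPhaseDeg,
                                trough_deg = dref@troughPhaseDeg)
  }

  trialsDf <- do.call(rbind, rows)
  trialsDf <- trialsDf[!is.na(trialsDf$mi), , drop = FALSE]
  groupDistributions <- lapply(names(pSums), function(g) {
    p <- pSums[[g]] / pN[[g]]
    p <- p / sum(p)
    centers <- (seq_len(nBins) - 0.5) * (360 / nBins)
    h <- shannonEntropy(p)
    new("PacDistribution", binCentersDeg = centers, p = p,
        mi = (log(nBins) - h) / log(nBins), entropy = h,
        peakPhaseDeg = centers[which.max(p)],
        troughPhaseDeg = centers[which.min(p)])
  })
  names(groupDistributions) <- names(pSums)

  gkey <- paste(trialsDf$odorant, trialsDf$stage, sep = ".")
  gsel <- trialsDf$stage != "intermediate"
  groups <- do.call(rbind, lapply(unique(gkey[gsel]), function(g) {
    sub <- trialsDf[gkey == g & gsel, ]
    data.frame(odorant = sub$odorant[1], stage = sub$stage[1],
               n_trials = length(unique(sub$trial)),
               mean_mi = mean(sub$mi),
               peak_deg = groupDistributions[[g]]@peakPhaseDeg,
               trough_deg = groupDistributions[[g]]@troughPhaseDeg,
               peak_angle_variance =
                 if (nrow(sub) >= 2) peakAngleVariance(sub$peak_deg) else NA_real_)
  }))

  list(trials = trialsDf, reference = do.call(rbind, refRows),
       groups = groups, groupDistributions = groupDistributions)
}
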
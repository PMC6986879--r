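#' @import methods
NULL

## ---------------------------------------------------------------------------
## BandSpec
## ---------------------------------------------------------------------------

#' Frequency band specification
#'
#' A named frequency band. Defaults used throughout the package are
#' theta 6--14 Hz (carrier), beta 15--30 Hz and high gamma 65--95 Hz
#' (fast bands whose amplitude is coupled to theta phase). A wider
#' 2--14 Hz theta variant is available from [defaultBands()].
#'
#' @slot name band name.
#' @slot lowHz,highHz band edges in Hz.
#' @aliases BandSpec
#' @export
setClass("BandSpec",
         representation(name = "character", lowHz = "numeric",
                        highHz = "numeric"),
         validity = function(object) {
           if (length(object@lowHz) != 1 || length(object@highHz) != 1)
             return("band edges must be scalars")
           if (!(object@lowHz > 0 && object@lowHz < object@highHz))
             return("need 0 < lowHz < highHz")
           TRUE
         })

#' @param name band name.
#' @param lowHz,highHz band edges in Hz.
#' @rdname BandSpec-class
#' @export
bandSpec <- function(name, lowHz, highHz) {
  new("BandSpec", name = as.character(name), lowHz = as.numeric(lowHz),
      highHz = as.numeric(highHz))
}

#' Standard analysis bands
#'
#' @return named list of [BandSpec-class] objects: \code{theta} (6--14 Hz),
#'   \code{theta_wide} (2--14 Hz), \code{beta} (15--30 Hz),
#'   \code{high_gamma} (65--95 Hz), and \code{low_gamma_sim} (30--50 Hz,
#'   the amplitude band used to analyse the 40 Hz two-oscillation
#'   simulation).
#' @export
defaultBands <- function() {
  list(theta = bandSpec("theta", 6, 14),
       theta_wide = bandSpec("theta_wide", 2, 14),
       beta = bandSpec("beta", 15, 30),
       high_gamma = bandSpec("high_gamma", 65, 95),
       low_gamma_sim = bandSpec("low_gamma_sim", 30, 50))
}

## accept either a BandSpec or c(low, high)
as_band <- function(band, name = "band") {
  if (is(band, "BandSpec")) return(band)
  if (is.numeric(band) && length(band) == 2) return(bandSpec(name, band[1], band[2]))
  if (is.character(band) && length(band) == 1) {
    bands <- defaultBands()
    if (band %in% names(bands)) return(bands[[band]])
  }
  stop("cannot interpret 'band': give a BandSpec, c(low, high) or a default band name")
}

## ---------------------------------------------------------------------------
## AnalysisConfig
## ---------------------------------------------------------------------------

#' Analysis configuration
#'
#' Bundles the tunable parameters shared across pipeline stages. All times
#' are in seconds relative to odor onset (diversion of the final valve
#' towards the animal, t = 0).
#'
#' @slot bands named list of [BandSpec-class].
#' @slot nPhaseBins number of phase bins for PAC distributions (default 51).
#' @slot timebinS width of the trial-aligned analysis grid (default 0.1 s).
#' @slot trialWindowS trial-aligned window covered by PRP and decoding
#'   (default c(-1.5, 4)).
#' @slot odorWindowS odor-delivery scoring window (default c(0.5, 2.5)).
#' @slot baselineWindowS pre-trial baseline window (default c(-1, 0)).
#' @slot pacWindowS per-trial window for PAC statistics (default c(0, 2.5)).
#' @slot responseStartS onset of the four 0.5 s lick-response blocks
#'   relative to odor onset (default 0.5).
#' @slot filterOrder Butterworth prototype order (default 20).
#' @slot waveletCycles Morlet wavelet width in cycles (default 7).
#' @slot nBootstrap bootstrap resamples (default 1000).
#' @slot nShuffles label permutations for the decoder control (default 20).
#' @slot alpha significance level (default 0.05).
#' @slot odorOnsetOffsetS offset added to odor-valve times to approximate
#'   odor arrival at the nose (default 0; the valve diversion defines t = 0).
#' @slot rngSeed integer seed for all stochastic stages.
#' @aliases AnalysisConfig
#' @export
setClass("AnalysisConfig",
         representation(bands = "list", nPhaseBins = "numeric",
                        timebinS = "numeric", trialWindowS = "numeric",
                        odorWindowS = "numeric", baselineWindowS = "numeric",
                        pacWindowS = "numeric", responseStartS = "numeric",
                        filterOrder = "numeric", waveletCycles = "numeric",
                        nBootstrap = "numeric", nShuffles = "numeric",
                        alpha = "numeric", odorOnsetOffsetS = "numeric",
                        rngSeed = "numeric"),
         validity = function(object) {
           if (object@nPhaseBins < 3) return("nPhaseBins must be >= 3")
           if (object@timebinS <= 0) return("timebinS must be positive")
           if (object@odorWindowS[1] < object@trialWindowS[1] ||
               object@odorWindowS[2] > object@trialWindowS[2])
             return("odorWindowS must lie within trialWindowS")
           TRUE
         })

#' @param ... named slot overrides, e.g. \code{nPhaseBins = 25}.
#' @rdname AnalysisConfig-class
#' @export
analysisConfig <- function(...) {
  defaults <- list(bands = defaultBands(), nPhaseBins = 51, timebinS = 0.1,
                   trialWindowS = c(-1.5, 4), odorWindowS = c(0.5, 2.5),
                   baselineWindowS = c(-1, 0), pacWindowS = c(0, 2.5),
                   responseStartS = 0.5, filterOrder = 20, waveletCycles = 7,
                   nBootstrap = 1000, nShuffles = 20, alpha = 0.05,
                   odorOnsetOffsetS = 0, rngSeed = 1)
  args <- list(...)
  bad <- setdiff(names(args), names(defaults))
  if (length(bad)) stop("unknown AnalysisConfig field(s): ",
                        paste(bad, collapse = ", "))
  defaults[names(args)] <- args
  do.call(new, c(list(Class = "AnalysisConfig"), defaults))
}

## ---------------------------------------------------------------------------
## LfpSession
## ---------------------------------------------------------------------------

#' Continuous multi-electrode LFP session
#'
#' Holds the continuous voltage traces for one recording session, the
#' session event timeline and the lick trace. Samples are stored as an
#' electrodes x time matrix in microvolts.
#'
#' @slot samples electrodes x time numeric matrix (uV).
#' @slot rate sampling frequency in Hz.
#' @slot events data.frame with columns \code{label}, \code{time_s}.
#' @slot lickTrace numeric lick signal (binary or volts), sampled at
#'   \code{rate}; may be empty.
#' @slot sessionId,subjectId identifiers.
#' @aliases LfpSession
#' @export
setClass("LfpSession",
         representation(samples = "matrix", rate = "numeric",
                        events = "data.frame", lickTrace = "numeric",
                        sessionId = "character", subjectId = "character"),
         validity = function(object) {
           if (length(object@rate) != 1 || object@rate <= 0)
             return("rate must be a positive scalar")
           if (anyNA(object@samples) || !all(is.finite(object@samples)))
             return("samples contain NA or non-finite values")
           dur <- ncol(object@samples) / object@rate
           if (nrow(object@events) &&
               (any(object@events$time_s < 0) ||
                any(object@events$time_s > dur)))
             return("event times must lie within [0, duration]")
           if (length(object@lickTrace) &&
               length(object@lickTrace) != ncol(object@samples))
             return("lickTrace must be empty or match the sample count")
           TRUE
         })

#' @param samples electrodes x time matrix (uV).
#' @param rate sampling rate (Hz).
#' @param events data.frame(label, time_s); default empty.
#' @param lickTrace numeric lick signal (optional).
#' @param sessionId,subjectId identifiers.
#' @rdname LfpSession-class
#' @export
lfpSession <- function(samples, rate = 20000,
                       events = data.frame(label = character(),
                                           time_s = numeric()),
                       lickTrace = numeric(0),
                       sessionId = "session", subjectId = "subject") {
  new("LfpSession", samples = samples, rate = as.numeric(rate),
      events = events, lickTrace = as.numeric(lickTrace),
      sessionId = sessionId, subjectId = subjectId)
}

## ---------------------------------------------------------------------------
## TrialTable
## ---------------------------------------------------------------------------

valid_outcomes <- c("Hit", "Miss", "CR", "FA", "undefined")

#' Per-trial behavioral table
#'
#' One row per completed trial. \code{odor_on_s} (the time the final valve
#' diverts the odorant towards the animal) defines t = 0 of trial-aligned
#' time. Outcomes follow the go/no-go decision tree: Hit/Miss for the
#' rewarded odorant (S+), CR/FA for the unrewarded odorant (S-);
#' \code{undefined} marks aborted trials, which every downstream stage
#' excludes. Sliding-window performance and the naive/intermediate/
#' proficient stage labels are computed on construction.
#'
#' @slot trials data.frame with columns \code{trial_start_s},
#'   \code{odor_on_s}, \code{odorant} ("S+"/"S-"), \code{outcome},
#'   \code{reinforced}, and a list column \code{lick_times} of absolute
#'   lick times (s).
#' @slot percentCorrect per-trial sliding performance (\%).
#' @slot stage per-trial label: "naive", "intermediate" or "proficient".
#' @aliases TrialTable
#' @export
setClass("TrialTable",
         representation(trials = "data.frame", percentCorrect = "numeric",
                        stage = "character"),
         validity = function(object) {
           tr <- object@trials
           need <- c("trial_start_s", "odor_on_s", "odorant", "outcome",
                     "reinforced", "lick_times")
           if (!all(need %in% names(tr)))
             return(paste("trials missing column(s):",
                          paste(setdiff(need, names(tr)), collapse = ", ")))
           if (!all(tr$odorant %in% c("S+", "S-")))
             return("odorant labels must be 'S+' or 'S-'")
           if (!all(tr$outcome %in% valid_outcomes))
             return("invalid outcome label")
           if (any(tr$odor_on_s < tr$trial_start_s))
             return("odor_on_s must be >= trial_start_s")
           bad <- (tr$odorant == "S+" & tr$outcome %in% c("CR", "FA")) |
             (tr$odorant == "S-" & tr$outcome %in% c("Hit", "Miss"))
           if (any(bad))
             return("outcome inconsistent with odorant (Hit/Miss are S+ outcomes, CR/FA are S- outcomes)")
           if (length(object@percentCorrect) != nrow(tr) ||
               length(object@stage) != nrow(tr))
             return("percentCorrect and stage must have one entry per trial")
           if (length(object@percentCorrect) &&
               (min(object@percentCorrect) < 0 ||
                max(object@percentCorrect) > 100))
             return("percentCorrect must lie in [0, 100]")
           TRUE
         })

#' @param trials data.frame as described above. If the \code{outcome}
#'   column is absent, outcomes are recomputed from the lick times with
#'   [classifyOutcome()] and the table is flagged with
#'   \code{attr(trialData(x), "derived_outcomes")}.
#' @param config [AnalysisConfig-class] supplying the response-window
#'   geometry used when outcomes must be derived.
#' @param performanceWindow sliding-performance window in trials (default 20).
#' @rdname TrialTable-class
#' @export
trialTable <- function(trials, config = analysisConfig(),
                       performanceWindow = 20) {
  if (!is.data.frame(trials)) stop("trials must be a data.frame")
  if (is.null(trials$lick_times))
    trials$lick_times <- replicate(nrow(trials), numeric(0), simplify = FALSE)
  derived <- FALSE
  if (is.null(trials$outcome)) {
    if (is.null(trials$odorant)) stop("odorant column is required")
    trials$outcome <- vapply(seq_len(nrow(trials)), function(i) {
      classifyOutcome(trials$odorant[i],
                      trials$lick_times[[i]] - trials$odor_on_s[i],
                      responseStartS = config@responseStartS)
    }, character(1))
    derived <- TRUE
  }
  if (is.null(trials$reinforced))
    trials$reinforced <- trials$outcome == "Hit"
  pc <- slidingPerformance(trials$outcome, window = performanceWindow)
  st <- segmentStages(pc)
  if (derived) attr(trials, "derived_outcomes") <- TRUE
  new("TrialTable", trials = trials, percentCorrect = as.numeric(pc),
      stage = st)
}

## ---------------------------------------------------------------------------
## PacDistribution
## ---------------------------------------------------------------------------

#' Amplitude-by-phase distribution with modulation index
#'
#' The normalized distribution of fast-band amplitude over carrier-phase
#' bins, together with the Kullback-Leibler modulation index
#' \eqn{MI = (\ln N - H)/\ln N}, the Shannon entropy \eqn{H} of the
#' distribution (nats), and the peak and trough phases (bin centers of the
#' maximal and minimal mean amplitude).
#'
#' @slot binCentersDeg phase bin centers in degrees, in [0, 360).
#' @slot p normalized mean-amplitude distribution (sums to 1).
#' @slot mi modulation index in [0, 1].
#' @slot entropy Shannon entropy of \code{p} in nats.
#' @slot peakPhaseDeg,troughPhaseDeg phases of max and min of \code{p}.
#' @aliases PacDistribution
#' @export
setClass("PacDistribution",
         representation(binCentersDeg = "numeric", p = "numeric",
                        mi = "numeric", entropy = "numeric",
                        peakPhaseDeg = "numeric", troughPhaseDeg = "numeric"),
         validity = function(object) {
           if (length(object@p) != length(object@binCentersDeg))
             return("p and binCentersDeg lengths differ")
           if (any(object@p < 0)) return("p must be nonnegative")
           if (abs(sum(object@p) - 1) > 1e-12)
             return("p must sum to 1 (within 1e-12)")
           n <- length(object@p)
           if (abs(object@mi - (log(n) - object@entropy) / log(n)) > 1e-9)
             return("mi inconsistent with entropy")
           if (object@peakPhaseDeg != object@binCentersDeg[which.max(object@p)])
             return("peakPhaseDeg is not the bin center of max(p)")
           if (object@troughPhaseDeg != object@binCentersDeg[which.min(object@p)])
             return("troughPhaseDeg is not the bin center of min(p)")
           TRUE
         })

## ---------------------------------------------------------------------------
## PrpTensor
## ---------------------------------------------------------------------------

#' Phase-referenced power tensor
#'
#' Trials x electrodes x time-bins phase-referenced power in dB, on the
#' trial-aligned 0.1 s grid, for one reference phase (peak or trough of
#' the PAC distribution) and one fast band. Trial metadata (odorant,
#' stage, outcome) travels with the tensor.
#'
#' @slot valuesDb numeric 3-d array, trials x electrodes x time bins.
#' @slot reference "peak" or "trough".
#' @slot band the fast [BandSpec-class].
#' @slot timebinsS bin centers (s, trial-aligned).
#' @slot odorWindowMeanDb trials x electrodes mean PRP over the odor window.
#' @slot trialInfo data.frame with per-trial \code{odorant}, \code{stage},
#'   \code{outcome}.
#' @slot referencePhases data.frame with per-electrode reference phase
#'   (deg) actually used.
#' @aliases PrpTensor
#' @export
setClass("PrpTensor",
         representation(valuesDb = "array", reference = "character",
                        band = "BandSpec", timebinsS = "numeric",
                        odorWindowMeanDb = "matrix", trialInfo = "data.frame",
                        referencePhases = "data.frame"),
         validity = function(object) {
           d <- dim(object@valuesDb)
           if (length(d) != 3) return("valuesDb must be a 3-d array")
           if (length(object@timebinsS) != d[3])
             return("timebinsS length must match dim 3 of valuesDb")
           if (anyNA(object@valuesDb))
             return("valuesDb must be gap-free (NAs are interpolated on construction)")
           if (!object@reference %in% c("peak", "trough"))
             return("reference must be 'peak' or 'trough'")
           if (nrow(object@trialInfo) != d[1])
             return("trialInfo must have one row per trial")
           dt <- diff(object@timebinsS)
           if (length(dt) && max(abs(dt - dt[1])) > 1e-9)
             return("time grid must be uniform")
           TRUE
         })

## ---------------------------------------------------------------------------
## Result containers
## ---------------------------------------------------------------------------

#' Per-time-bin decoding results
#'
#' Leave-one-out LDA accuracy per trial-aligned 0.1 s bin, the
#' label-shuffle control band, per-outcome accuracy, PC1 group time
#' courses, the normalized area under the accuracy curve, and the held-out
#' per-trial predictions the decision-time stage consumes.
#'
#' @slot timebinsS bin centers (s).
#' @slot accuracy percent correct per bin.
#' @slot shuffledMean,shuffledLo,shuffledHi shuffle-control mean and 95\%
#'   band per bin.
#' @slot perOutcome bins x outcome matrix of percent correct.
#' @slot pc1 data.frame of PC1 group means and CIs per bin.
#' @slot auc normalized area under the accuracy curve over the odor window.
#' @slot predictedSplus trials x bins logical matrix: held-out prediction
#'   was S+.
#' @slot trialInfo per-trial odorant/stage/outcome.
#' @aliases DecodingTimecourse
#' @export
setClass("DecodingTimecourse",
         representation(timebinsS = "numeric", accuracy = "numeric",
                        shuffledMean = "numeric", shuffledLo = "numeric",
                        shuffledHi = "numeric", perOutcome = "matrix",
                        pc1 = "data.frame", auc = "numeric",
                        predictedSplus = "matrix", trialInfo = "data.frame"))

#' Rank-sum p-value time course
#'
#' @slot timebinsS bin centers (s).
#' @slot p two-sided rank-sum p-value per bin.
#' @slot source one of "licks", "lda_peak", "lda_trough" (or a custom tag).
#' @slot decisionTimeS earliest sustained sub-alpha crossing (s), or NA.
#' @aliases PValueSeries
#' @export
setClass("PValueSeries",
         representation(timebinsS = "numeric", p = "numeric",
                        source = "character", decisionTimeS = "numeric"),
         validity = function(object) {
           if (length(object@p) != length(object@timebinsS))
             return("p and timebinsS lengths differ")
           pp <- object@p[!is.na(object@p)]
           if (length(pp) && (min(pp) <= 0 || max(pp) > 1))
             return("p values must lie in (0, 1]")
           TRUE
         })

#' Participation-ratio dimensionality time course
#'
#' @slot timebinsS bin centers (s).
#' @slot curves long data.frame: \code{group}, \code{timebin_s},
#'   \code{dim}, \code{normalized_dim}.
#' @slot nChannels number of input channels M.
#' @aliases DimTimecourse
#' @export
setClass("DimTimecourse",
         representation(timebinsS = "numeric", curves = "data.frame",
                        nChannels = "numeric"))

#' Percentile bootstrap confidence interval
#'
#' @slot point sample mean.
#' @slot lo,hi percentile bounds.
#' @slot nResamples number of bootstrap resamples.
#' @aliases BootstrapCI
#' @export
setClass("BootstrapCI",
         representation(point = "numeric", lo = "numeric", hi = "numeric",
                        nResamples = "numeric"),
         validity = function(object) {
           if (!(object@lo <= object@point && object@point <= object@hi))
             return("need lo <= point <= hi")
           TRUE
         })
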
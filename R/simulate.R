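## ---------------------------------------------------------------------------
## Two-oscillation PAC simulation
## ---------------------------------------------------------------------------

#' Configuration for the two-oscillation PAC simulation
#'
#' Parameterizes the canonical validation signal: a low-frequency cosine
#' carrier (8 Hz) plus a high-frequency cosine (40 Hz) that is either of
#' constant amplitude (\code{coupling = "none"}) or multiplied by a
#' periodic train of gaussian bursts of full width at half maximum
#' \code{(1/fLow)/2} centered at a fixed carrier phase
#' (\code{coupling = "burst"}, default 180 degrees).
#'
#' The coupled signal retains a constant 40 Hz component of amplitude
#' \code{baselineHighAmp} beneath the bursts. Its default (0.58, relative
#' to \code{burstAmp = 1}) is the ratio at which the amplitude-by-phase
#' distribution of this construction yields a modulation index of about
#' 0.01, the strength conventionally used to illustrate clearly coupled
#' oscillations; the burst-to-baseline ratio is otherwise unconstrained.
#'
#' Three coupling modes are supported: \code{"burst"} (bursts at a fixed
#' carrier phase -- genuine PAC), \code{"uniform"} (one burst per carrier
#' cycle at an independently uniform random phase -- the matched no-PAC
#' control, whose residual modulation index reflects only finite-sampling
#' noise), and \code{"none"} (a constant-amplitude fast cosine). The
#' \code{"uniform"} mode draws its burst phases from \code{rngSeed}, so it
#' is deterministic for a fixed configuration.
#'
#' @slot fLow,fHigh carrier and fast frequencies (Hz; defaults 8 and 40).
#' @slot coupling "none", "uniform" or "burst".
#' @slot burstCenterDeg carrier phase of the burst centers (default 180).
#' @slot burstFwhmS burst full width at half maximum in seconds
#'   (default (1/fLow)/2 = 62.5 ms).
#' @slot baselineHighAmp constant 40 Hz amplitude under the bursts.
#' @slot burstAmp burst amplitude (also the amplitude of the constant
#'   fast cosine when \code{coupling = "none"}).
#' @slot durationS signal duration (s, default 20).
#' @slot rate sampling rate (Hz, default 20000).
#' @slot rngSeed seed for the "uniform" mode's burst phases (default 1).
#' @aliases SimulationConfig
#' @export
setClass("SimulationConfig",
         representation(fLow = "numeric", fHigh = "numeric",
                        coupling = "character", burstCenterDeg = "numeric",
                        burstFwhmS = "numeric", baselineHighAmp = "numeric",
                        burstAmp = "numeric", durationS = "numeric",
                        rate = "numeric", rngSeed = "numeric"),
         validity = function(object) {
           if (!object@coupling %in% c("none", "uniform", "burst"))
             return("coupling must be 'none', 'uniform' or 'burst'")
           if (object@burstFwhmS <= 0) return("burstFwhmS must be positive")
           if (object@rate <= 2 * object@fHigh)
             return("rate must exceed 2 * fHigh")
           if (object@fLow <= 0 || object@fHigh <= object@fLow)
             return("need 0 < fLow < fHigh")
           TRUE
         })

#' @param fLow,fHigh,coupling,burstCenterDeg,burstFwhmS,baselineHighAmp,burstAmp,durationS,rate,rngSeed
#'   see the class slots.
#' @rdname SimulationConfig-class
#' @export
simulationConfig <- function(fLow = 8, fHigh = 40,
                             coupling = c("none", "uniform", "burst"),
                             burstCenterDeg = 180,
                             burstFwhmS = (1 / fLow) / 2,
                             baselineHighAmp = 0.58, burstAmp = 1,
                             durationS = 20, rate = 20000, rngSeed = 1) {
  new("SimulationConfig", fLow = fLow, fHigh = fHigh,
      coupling = match.arg(coupling), burstCenterDeg = burstCenterDeg,
      burstFwhmS = burstFwhmS, baselineHighAmp = baselineHighAmp,
      burstAmp = burstAmp, durationS = durationS, rate = rate,
      rngSeed = rngSeed)
}

## periodic gaussian burst train: unit-peak gaussians of sd sigma (s)
## centered at carrier phase centerDeg of every cycle of frequency fLow.
## phase01: carrier phase in cycles (can exceed 1).
gaussBurstTrain <- function(phase01, fLow, centerDeg, sigmaS) {
  u <- (phase01 - centerDeg / 360) %% 1   # cycles past the nearest center
  g <- 0
  for (k in -3:3) g <- g + exp(-((u + k) / fLow)^2 / (2 * sigmaS^2))
  g
}

#' Simulate the two-oscillation PAC validation signal
#'
#' Deterministically generates the signal described by a
#' [SimulationConfig-class]: \code{coupling = "none"} gives
#' \eqn{\cos(2\pi f_{low} t) + A\cos(2\pi f_{high} t)}; \code{"burst"}
#' adds gaussian-windowed fast bursts centered at a fixed carrier phase
#' each cycle, on top of a constant fast baseline.
#'
#' @param config a [SimulationConfig-class].
#' @return list with \code{signal}, \code{t} (s), \code{phaseDeg} (true
#'   carrier phase, cosine convention), \code{envelopeTruth} (true fast
#'   amplitude), and \code{config}.
#' @examples
#' sim <- simulatePacSignal(simulationConfig(durationS = 2, rate = 2000))
#' @export
simulatePacSignal <- function(config = simulationConfig()) {
  n <- round(config@durationS * config@rate)
  t <- (seq_len(n) - 1) / config@rate
  phase01 <- config@fLow * t
  low <- cos(2 * pi * phase01)
  sigma <- config@burstFwhmS / (2 * sqrt(2 * log(2)))
  if (config@coupling == "none") {
    env <- rep(config@burstAmp, n)
  } else if (config@coupling == "burst") {
    env <- config@baselineHighAmp +
      config@burstAmp * gaussBurstTrain(phase01, config@fLow,
                                        config@burstCenterDeg, sigma)
  } else {
    ## one burst per carrier cycle at an independent uniform phase
    nCycles <- ceiling(config@durationS * config@fLow)
    centers <- withLocalSeed(config@rngSeed, {
      (seq_len(nCycles) - 1 + stats::runif(nCycles)) / config@fLow
    })
    env <- rep(config@baselineHighAmp, n)
    for (ck in centers) {
      i0 <- max(1L, floor((ck - 4 * sigma) * config@rate) + 1L)
      i1 <- min(n, ceiling((ck + 4 * sigma) * config@rate) + 1L)
      if (i0 > n) next
      seg <- i0:i1
      env[seg] <- env[seg] +
        config@burstAmp * exp(-(t[seg] - ck)^2 / (2 * sigma^2))
    }
  }
  list(signal = low + env * cos(2 * pi * config@fHigh * t), t = t,
       phaseDeg = wrap360(phase01 * 360), envelopeTruth = env,
       config = config)
}

## ---------------------------------------------------------------------------
## Full go/no-go session simulation
## ---------------------------------------------------------------------------

#' Configuration for a synthetic go/no-go session
#'
#' Parameterizes a full multi-electrode session with the statistical
#' structure the analysis pipeline assumes: a jittered theta carrier
#' shared across electrodes; beta and high-gamma bursts whose coupling
#' strength (expressed as a target modulation index), coupling phase
#' (with von Mises across-trial jitter) and odor-epoch amplitude gain
#' depend on the odorant; per-trial latent log-amplitude factors mixed
#' into the electrodes through an orthonormal matrix, which sets the
#' participation-ratio dimensionality of the electrode space; white
#' sensor noise; and lick trains that diverge between S+ and S- at a
#' configurable latency.
#'
#' Three profiles bundle the study conditions: \code{"proficient"}
#' (strong, phase-locked S+ coupling, +6/-6 dB odor gains, early S- lick
#' stop, latent collapse to one shared factor during odor),
#' \code{"naive"} (weak symmetric coupling, no odor gain, late S- lick
#' stop, high false-alarm rate) and \code{"null"} (S- statistically
#' identical to S+ in every respect -- the negative control).
#'
#' Odorant-keyed slots are named lists with entries \code{"S+"} and
#' \code{"S-"}.
#'
#' @slot profile "proficient", "naive" or "null".
#' @slot nElectrodes,nTrials electrodes (default 16) and trials (default 100).
#' @slot rate sampling rate (Hz, default 1000).
#' @slot trialPeriodS trial spacing (s, default 7); odor onset sits 2.5 s
#'   into each slot.
#' @slot thetaFreqHz,thetaFreqJitterHz,thetaAmp theta carrier frequency
#'   (8 Hz), per-trial frequency jitter sd, amplitude (uV).
#' @slot bandAmps named list of fast-band burst base amplitudes (uV).
#' @slot miTarget odorant-keyed target modulation index of the bursts.
#' @slot peakPhaseDeg odorant-keyed coupling phase (deg).
#' @slot phaseJitterKappa odorant-keyed von Mises concentration of the
#'   across-trial coupling-phase jitter (0 = uniform).
#' @slot odorGainDb odorant-keyed amplitude gain (dB) applied to the fast
#'   bands during the odor epoch.
#' @slot baselineMi,baselinePhaseDeg,baselineKappa coupling outside the
#'   odor epoch, shared by both odorants (so nothing about the upcoming
#'   odorant is readable before odor onset).
#' @slot nLatentSources latent factors mixed into the electrodes
#'   (default 3).
#' @slot latentLogSdDb per-channel sd of the latent log-amplitude
#'   fluctuations (dB, default 1.5).
#' @slot collapseDuringOdor collapse the latent space to one shared
#'   factor during the odor epoch (logical).
#' @slot sensorNoiseDb white-noise amplitude re the high-gamma burst
#'   amplitude (dB, default -10).
#' @slot lickRateHz,lickOnsetS steady lick rate (Hz) and lick onset after
#'   odor onset (s).
#' @slot sminusStopS time after odor onset at which S- licking stops on
#'   correct rejections (s) -- the built-in lick divergence latency.
#' @slot hitRate,faRate go-response probabilities for S+ and S-.
#' @slot rngSeed,sessionId,subjectId seed and identifiers.
#' @aliases SessionConfig
#' @export
setClass("SessionConfig",
         representation(profile = "character", nElectrodes = "numeric",
                        nTrials = "numeric", rate = "numeric",
                        trialPeriodS = "numeric", thetaFreqHz = "numeric",
                        thetaFreqJitterHz = "numeric", thetaAmp = "numeric",
                        bandAmps = "list", miTarget = "list",
                        peakPhaseDeg = "list", phaseJitterKappa = "list",
                        odorGainDb = "list", baselineMi = "numeric",
                        baselinePhaseDeg = "numeric",
                        baselineKappa = "numeric",
                        nLatentSources = "numeric",
                        latentLogSdDb = "numeric",
                        collapseDuringOdor = "logical",
                        sensorNoiseDb = "numeric", lickRateHz = "numeric",
                        lickOnsetS = "numeric", sminusStopS = "numeric",
                        hitRate = "numeric", faRate = "numeric",
                        rngSeed = "numeric", sessionId = "character",
                        subjectId = "character"),
         validity = function(object) {
           if (object@nLatentSources > object@nElectrodes)
             return("nLatentSources must be <= nElectrodes")
           if (object@hitRate < 0 || object@hitRate > 1 ||
               object@faRate < 0 || object@faRate > 1)
             return("hitRate and faRate must be probabilities")
           odk <- c("S+", "S-")
           for (f in c("miTarget", "peakPhaseDeg", "phaseJitterKappa",
                       "odorGainDb"))
             if (!all(odk %in% names(slot(object, f))))
               return(paste(f, "must be a list with entries 'S+' and 'S-'"))
           TRUE
         })

#' @param profile parameter bundle; see the class description.
#' @param ... named slot overrides (e.g. \code{nTrials = 40},
#'   \code{rngSeed = 7}).
#' @rdname SessionConfig-class
#' @export
sessionConfig <- function(profile = c("proficient", "naive", "null"), ...) {
  profile <- match.arg(profile)
  base <- list(profile = profile, nElectrodes = 16, nTrials = 100,
               rate = 1000, trialPeriodS = 7, thetaFreqHz = 8,
               thetaFreqJitterHz = 0.3, thetaAmp = 50,
               bandAmps = list(high_gamma = 20, beta = 25),
               baselineMi = 0.01, baselinePhaseDeg = 120,
               baselineKappa = 30,
               nLatentSources = 3, latentLogSdDb = 1.5,
               sensorNoiseDb = -10, lickRateHz = 7, lickOnsetS = 0.1,
               rngSeed = 1, sessionId = paste0("sim-", profile),
               subjectId = "sim-mouse")
  prof <- switch(profile,
    proficient = list(miTarget = list("S+" = 0.02, "S-" = 0.014),
                      peakPhaseDeg = list("S+" = 120, "S-" = 120),
                      phaseJitterKappa = list("S+" = 20, "S-" = 2),
                      odorGainDb = list("S+" = 6, "S-" = -6),
                      collapseDuringOdor = TRUE,
                      sminusStopS = 0.25, hitRate = 0.95, faRate = 0.10),
    naive = list(miTarget = list("S+" = 0.01, "S-" = 0.01),
                 peakPhaseDeg = list("S+" = 120, "S-" = 120),
                 phaseJitterKappa = list("S+" = 4, "S-" = 4),
                 odorGainDb = list("S+" = 0, "S-" = 0),
                 collapseDuringOdor = FALSE,
                 sminusStopS = 1.5, hitRate = 0.90, faRate = 0.80),
    null = list(miTarget = list("S+" = 0.02, "S-" = 0.02),
                peakPhaseDeg = list("S+" = 120, "S-" = 120),
                phaseJitterKappa = list("S+" = 20, "S-" = 20),
                odorGainDb = list("S+" = 6, "S-" = 6),
                collapseDuringOdor = TRUE,
                sminusStopS = 0.25, hitRate = 0.95, faRate = 0.95))
  args <- c(base, prof)
  over <- list(...)
  bad <- setdiff(names(over), names(args))
  if (length(bad)) stop("unknown SessionConfig field(s): ",
                        paste(bad, collapse = ", "))
  args[names(over)] <- over
  do.call(new, c(list(Class = "SessionConfig"), args))
}

#' Invert a target modulation index to a burst modulation depth
#'
#' Finds the depth d such that the phase-domain envelope
#' \eqn{1 + d\,g(\phi)} (g = periodic gaussian burst of FWHM half a
#' cycle) has the requested 51-bin modulation index. Used by the session
#' generator to express coupling strength on the MI scale.
#'
#' @param miTarget target modulation index (0 gives depth 0).
#' @param sigmaCycles burst sd in cycles (default FWHM/2 = 0.5 cycle,
#'   i.e. 0.2123).
#' @param nBins phase bins (default 51).
#' @return nonnegative depth.
#' @export
miToDepth <- function(miTarget, sigmaCycles = 0.5 / (2 * sqrt(2 * log(2))),
                      nBins = 51) {
  if (miTarget <= 0) return(0)
  phi <- (seq_len(4096) - 0.5) / 4096
  g <- phaseGauss(phi, 0.5, sigmaCycles)
  bin <- ceiling(phi * nBins)
  miOf <- function(d) {
    p <- as.numeric(tapply(1 + d * g, bin, mean))
    modulationIndex(p / sum(p))
  }
  if (miOf(1e3) < miTarget)
    stop("miTarget ", miTarget, " not attainable by this burst shape")
  stats::uniroot(function(d) miOf(d) - miTarget, c(1e-8, 1e3),
                 tol = 1e-10)$root
}

## periodic unit-peak gaussian in phase (cycles)
phaseGauss <- function(phase01, centerCycles, sigmaCycles) {
  u <- (phase01 - centerCycles) %% 1
  g <- 0
  for (k in -2:2) g <- g + exp(-((u + k))^2 / (2 * sigmaCycles^2))
  g
}

## von Mises sampler (Best & Fisher rejection); kappa ~ 0 gives uniform
rVonMisesDeg <- function(n, muDeg, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (u[2] < cc * (2 - cc) || log(cc) - log(u[2]) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- (muDeg + sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1)) *
                   180 / pi) %% 360
    }
  }
  out
}

#' Simulate a full go/no-go session
#'
#' Generates an [LfpSession-class], its [TrialTable-class] and a
#' ground-truth record from a [SessionConfig-class]. Outcomes are not
#' assigned directly: lick trains are generated from the behavioral
#' model and outcomes emerge from [classifyOutcome()], so the configured
#' hit and false-alarm probabilities are realized in expectation.
#'
#' @param config a [SessionConfig-class].
#' @return list with \code{session}, \code{trials} (TrialTable) and
#'   \code{truth} (per-trial coupling phases, depths, gains, the mixing
#'   matrix, latent count and lick divergence latency).
#' @examples
#' \donttest{
#' sim <- simulateSession(sessionConfig(nTrials = 20, nElectrodes = 4))
#' }
#' @export
simulateSession <- function(config = sessionConfig()) {
  withLocalSeed(config@rngSeed, simulateSessionImpl(config))
}

simulateSessionImpl <- function(config) {
  rate <- config@rate
  nT <- config@nTrials
  nEl <- config@nElectrodes
  period <- config@trialPeriodS
  lead <- 2
  durationS <- lead + nT * period + 2
  n <- round(durationS * rate)
  t <- (seq_len(n) - 1) / rate
  odorOn <- lead + (seq_len(nT) - 1) * period + 2.5

  ## odorant sequence: blocks of 20 with 10 S+ / 10 S- in random order
  odorant <- unlist(lapply(seq_len(ceiling(nT / 20)), function(b)
    sample(rep(c("S+", "S-"), 10))))[seq_len(nT)]

  ## theta carrier: per-trial-slot frequency jitter, continuous phase
  slot <- pmin(pmax(floor((t - lead) / period) + 1, 1), nT)
  fTheta <- config@thetaFreqHz +
    stats::rnorm(nT, 0, config@thetaFreqJitterHz)
  fTheta <- pmin(pmax(fTheta, 6.5), 11)
  instF <- fTheta[slot]
  phase01 <- cumsum(instF) / rate
  theta <- config@thetaAmp * cos(2 * pi * phase01)

  ## latent mixing matrix: orthonormal columns
  V <- qr.Q(qr(matrix(stats::rnorm(nEl * config@nLatentSources), nEl)))
  latSd <- config@latentLogSdDb * sqrt(nEl / config@nLatentSources)

  depth <- lapply(config@miTarget, miToDepth)
  dBase <- miToDepth(config@baselineMi)
  sigmaCyc <- 0.5 / (2 * sqrt(2 * log(2)))
  gbar <- mean(phaseGauss((seq_len(4096) - 0.5) / 4096, 0.5, sigmaCyc))

  carriers <- list(high_gamma = 80, beta = 22)
  samples <- matrix(rep(theta, nEl), nrow = nEl, byrow = TRUE)
  psi <- numeric(nT)
  lickTimes <- vector("list", nT)
  go <- logical(nT)

  for (i in seq_len(nT)) {
    od <- odorant[i]
    psi[i] <- rVonMisesDeg(1, config@peakPhaseDeg[[od]],
                           config@phaseJitterKappa[[od]])
    i0 <- round((odorOn[i] - 2.5) * rate) + 1
    i1 <- min(n, round((odorOn[i] + 4.5) * rate))
    win <- i0:i1
    twin <- t[win] - odorOn[i]
    d <- depth[[od]]
    inOdor <- twin >= 0 & twin < 2.5
    ## odorant-specific coupling only during the odor epoch; shared
    ## baseline coupling before and after
    psiBase <- rVonMisesDeg(1, config@baselinePhaseDeg,
                            config@baselineKappa)
    gOdor <- phaseGauss(phase01[win], psi[i] / 360, sigmaCyc)
    gBase <- phaseGauss(phase01[win], psiBase / 360, sigmaCyc)
    envUnit <- ifelse(inOdor,
                      (1 + d * gOdor) / (1 + d * gbar),
                      (1 + dBase * gBase) / (1 + dBase * gbar))
    gainLin <- 10^(config@odorGainDb[[od]] / 20)
    gainVec <- ifelse(inOdor, gainLin, 1)

    ## latent log-amplitude factors: independent baseline draw, and an
    ## odor-epoch draw that optionally collapses to one shared factor
    epsBase <- stats::rnorm(config@nLatentSources, 0, latSd)
    dbBase <- as.numeric(V %*% epsBase)
    if (config@collapseDuringOdor) {
      eta <- stats::rnorm(1, 0, latSd) * sqrt(config@nLatentSources)
      dbOdor <- V[, 1] * eta
    } else {
      dbOdor <- as.numeric(V %*% stats::rnorm(config@nLatentSources, 0,
                                              latSd))
    }

    for (bn in names(carriers)) {
      carrier <- cos(2 * pi * carriers[[bn]] * twin +
                       stats::runif(1, 0, 2 * pi))
      burst <- envUnit * carrier * gainVec * config@bandAmps[[bn]]
      for (m in seq_len(nEl)) {
        ampDb <- ifelse(inOdor, dbOdor[m], dbBase[m])
        samples[m, win] <- samples[m, win] + burst * 10^(ampDb / 20)
      }
    }

    ## licks
    ## steady licking with a random raster phase per trial (so lick
    ## probability is uniform over time across trials, not comb-like)
    regular <- function(from, to) {
      if (to <= from) return(numeric(0))
      start <- from + stats::runif(1, 0, 1 / config@lickRateHz)
      if (start > to) return(numeric(0))
      lt <- seq(start, to, by = 1 / config@lickRateHz)
      lt + stats::runif(length(lt), -0.02, 0.02)
    }
    isGo <- if (od == "S+") stats::runif(1) < config@hitRate
    else stats::runif(1) < config@faRate
    go[i] <- isGo
    lt <- if (isGo) regular(config@lickOnsetS, 2.9)
    else regular(config@lickOnsetS,
                 if (od == "S+") 0.35 else config@sminusStopS)
    lickTimes[[i]] <- sort(lt[lt >= 0]) + odorOn[i]
  }

  noiseSd <- config@bandAmps$high_gamma * 10^(config@sensorNoiseDb / 20)
  samples <- samples + matrix(stats::rnorm(length(samples), 0, noiseSd),
                              nrow = nEl)

  lickTrace <- numeric(n)
  li <- round(unlist(lickTimes) * rate) + 1
  for (kk in 0:4) lickTrace[pmin(pmax(li + kk, 1), n)] <- 1

  events <- data.frame(
    label = rep(c("odor_on", "odor_off"), each = nT),
    time_s = c(odorOn, odorOn + 2.5))
  events <- events[order(events$time_s), ]
  session <- lfpSession(samples, rate = rate, events = events,
                        lickTrace = lickTrace,
                        sessionId = config@sessionId,
                        subjectId = config@subjectId)
  trials <- data.frame(trial_start_s = odorOn - 2,
                       odor_on_s = odorOn, odorant = odorant)
  trials$lick_times <- lickTimes
  tt <- trialTable(trials)
  truth <- list(config = config, psiDeg = psi, depth = depth,
                miTarget = config@miTarget, odorGainDb = config@odorGainDb,
                nLatentSources = config@nLatentSources, mixing = V,
                lickDivergenceS = config@sminusStopS, go = go,
                thetaFreqHz = fTheta, odorOnS = odorOn)
  list(session = session, trials = tt, truth = truth)
}
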
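## Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, force(expr), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

## A small but complete "proficient" session with the full PAC -> PRP ->
## decoding chain, shared across test files.
smallProficientChain <- function() {
  fixture("smallProficient", {
    cfg <- analysisConfig(nBootstrap = 200, rngSeed = 5)
    sim <- simulateSession(sessionConfig("proficient", nTrials = 40,
                                         nElectrodes = 6, rngSeed = 42))
    pac <- sessionPac(sim$session, sim$trials, config = cfg)
    prp <- sessionPrp(sim$session, sim$trials, "high_gamma", "peak",
                      cfg, pac = pac)
    dec <- decodeTimecourse(prp, "proficient", cfg)
    list(cfg = cfg, sim = sim, pac = pac, prp = prp, dec = dec)
  })
}

## A 2-electrode toy session for I/O round trips.
toySession <- function() {
  fixture("toySession", {
    simulateSession(sessionConfig("proficient", nTrials = 4,
                                  nElectrodes = 2, nLatentSources = 2,
                                  rate = 500, trialPeriodS = 7,
                                  rngSeed = 9))
  })
}

## trial-aligned grid centers, written independently of the package
gridCentersForTest <- function(window, dt) {
  window[1] + (seq_len(round((window[2] - window[1]) / dt)) - 0.5) * dt
}

## deterministic phase series visiting every bin, plus an envelope that is
## an explicit function of phase
phaseEnvFixture <- function(n = 20000, fun = function(ph) 1 + 0 * ph) {
  ph <- (seq_len(n) * 360 * 7.3 / n) %% 360
  list(phaseDeg = ph, envelope = fun(ph))
}
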
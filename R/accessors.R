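#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @aliases samplingRate,LfpSession-method
setMethod("samplingRate", "LfpSession", function(x) x@rate)

#' @rdname accessors
#' @aliases electrodeCount,LfpSession-method
setMethod("electrodeCount", "LfpSession", function(x) nrow(x@samples))

#' @rdname accessors
#' @aliases lfpSamples,LfpSession-method
setMethod("lfpSamples", "LfpSession", function(x) x@samples)

#' @rdname accessors
#' @aliases sessionEvents,LfpSession-method
setMethod("sessionEvents", "LfpSession", function(x) x@events)

#' @rdname accessors
#' @aliases trialData,TrialTable-method
setMethod("trialData", "TrialTable", function(x) x@trials)

#' @rdname accessors
#' @aliases percentCorrect,TrialTable-method
setMethod("percentCorrect", "TrialTable", function(x) x@percentCorrect)

#' @rdname accessors
#' @aliases learningStage,TrialTable-method
setMethod("learningStage", "TrialTable", function(x) x@stage)

#' @rdname accessors
#' @aliases miValue,PacDistribution-method
setMethod("miValue", "PacDistribution", function(x) x@mi)

#' @rdname accessors
#' @aliases peakPhase,PacDistribution-method
setMethod("peakPhase", "PacDistribution", function(x) x@peakPhaseDeg)

#' @rdname accessors
#' @aliases troughPhase,PacDistribution-method
setMethod("troughPhase", "PacDistribution", function(x) x@troughPhaseDeg)

#' @rdname accessors
#' @aliases phaseDistribution,PacDistribution-method
setMethod("phaseDistribution", "PacDistribution", function(x)
  data.frame(bin_center_deg = x@binCentersDeg, p = x@p))

#' @rdname accessors
#' @aliases prpValues,PrpTensor-method
setMethod("prpValues", "PrpTensor", function(x) x@valuesDb)

#' @rdname accessors
#' @aliases timeBins,PrpTensor-method
setMethod("timeBins", "PrpTensor", function(x) x@timebinsS)

#' @rdname accessors
#' @aliases timeBins,DecodingTimecourse-method
setMethod("timeBins", "DecodingTimecourse", function(x) x@timebinsS)

#' @rdname accessors
#' @aliases timeBins,DimTimecourse-method
setMethod("timeBins", "DimTimecourse", function(x) x@timebinsS)

#' @rdname accessors
#' @aliases timeBins,PValueSeries-method
setMethod("timeBins", "PValueSeries", function(x) x@timebinsS)

#' @rdname accessors
#' @aliases trialData,PrpTensor-method
setMethod("trialData", "PrpTensor", function(x) x@trialInfo)

#' @rdname accessors
#' @aliases decodingAccuracy,DecodingTimecourse-method
setMethod("decodingAccuracy", "DecodingTimecourse", function(x)
  data.frame(timebin_s = x@timebinsS, accuracy = x@accuracy,
             shuffled_mean = x@shuffledMean, shuffled_lo = x@shuffledLo,
             shuffled_hi = x@shuffledHi))

#' @rdname accessors
#' @aliases pValues,PValueSeries-method
setMethod("pValues", "PValueSeries", function(x) x@p)

#' @rdname accessors
#' @aliases dimCurves,DimTimecourse-method
setMethod("dimCurves", "DimTimecourse", function(x) x@curves)

#' @rdname accessors
#' @aliases ciBounds,BootstrapCI-method
setMethod("ciBounds", "BootstrapCI", function(x)
  c(lo = x@lo, point = x@point, hi = x@hi))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "LfpSession", function(object) {
  cat("LfpSession '", object@sessionId, "' (subject ", object@subjectId,
      ")\n", sep = "")
  cat("  ", nrow(object@samples), " electrodes x ",
      ncol(object@samples), " samples @ ", object@rate, " Hz (",
      round(ncol(object@samples) / object@rate, 1), " s)\n", sep = "")
  cat("  ", nrow(object@events), " events; lick trace: ",
      if (length(object@lickTrace)) "yes" else "no", "\n", sep = "")
})

setMethod("show", "TrialTable", function(object) {
  tr <- object@trials
  cat("TrialTable with", nrow(tr), "trials\n")
  if (nrow(tr)) {
    cat("  odorants:", paste(names(table(tr$odorant)),
                             table(tr$odorant), collapse = ", "), "\n")
    cat("  outcomes:", paste(names(table(tr$outcome)),
                             table(tr$outcome), collapse = ", "), "\n")
    cat("  stages:  ", paste(names(table(object@stage)),
                             table(object@stage), collapse = ", "), "\n")
  }
})

setMethod("show", "PacDistribution", function(object) {
  cat("PacDistribution (", length(object@p), " bins): MI = ",
      signif(object@mi, 3), ", peak ", round(object@peakPhaseDeg, 1),
      " deg, trough ", round(object@troughPhaseDeg, 1), " deg\n", sep = "")
})

setMethod("show", "PrpTensor", function(object) {
  d <- dim(object@valuesDb)
  cat("PrpTensor [", object@reference, " / ", object@band@name, "]: ",
      d[1], " trials x ", d[2], " electrodes x ", d[3], " bins (",
      object@timebinsS[1], " to ", object@timebinsS[d[3]], " s)\n",
      sep = "")
})

setMethod("show", "DecodingTimecourse", function(object) {
  cat("DecodingTimecourse: ", length(object@timebinsS), " bins, peak accuracy ",
      round(max(object@accuracy), 1), "%, normalized AUC ",
      signif(object@auc, 3), "\n", sep = "")
})

setMethod("show", "PValueSeries", function(object) {
  cat("PValueSeries [", object@source, "]: ", length(object@p),
      " bins, decision time ",
      if (is.na(object@decisionTimeS)) "undefined"
      else paste0(object@decisionTimeS, " s"), "\n", sep = "")
})

setMethod("show", "DimTimecourse", function(object) {
  cat("DimTimecourse: M =", object@nChannels, "channels,",
      length(unique(object@curves$group)), "group(s),",
      length(object@timebinsS), "bins\n")
})

setMethod("show", "BootstrapCI", function(object) {
  cat("BootstrapCI: ", signif(object@point, 4), " [",
      signif(object@lo, 4), ", ", signif(object@hi, 4), "] (",
      object@nResamples, " resamples)\n", sep = "")
})

setMethod("show", "BandSpec", function(object) {
  cat("BandSpec '", object@name, "': ", object@lowHz, "-", object@highHz,
      " Hz\n", sep = "")
})

setMethod("show", "SessionConfig", function(object) {
  cat("SessionConfig [", object@profile, "]: ", object@nElectrodes,
      " electrodes, ", object@nTrials, " trials @ ", object@rate,
      " Hz, seed ", object@rngSeed, "\n", sep = "")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: ", object@fLow, " Hz carrier + ", object@fHigh,
      " Hz fast, coupling '", object@coupling, "', ", object@durationS,
      " s @ ", object@rate, " Hz\n", sep = "")
})
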
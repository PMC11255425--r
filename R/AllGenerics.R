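# Accessor generics and show methods. Slots are never reached into directly
# by user code; these accessors are the supported surface.

#' @rdname accessors
#' @export
setGeneric("scans", function(x) standardGeneric("scans"))
#' @rdname accessors
#' @export
setGeneric("scanTimes", function(x) standardGeneric("scanTimes"))
#' @rdname accessors
#' @export
setGeneric("waveform", function(x) standardGeneric("waveform"))
#' @rdname accessors
#' @export
setGeneric("gain", function(x) standardGeneric("gain"))
#' @rdname accessors
#' @export
setGeneric("channelId", function(x) standardGeneric("channelId"))
#' @rdname accessors
#' @export
setGeneric("rampDuration", function(x) standardGeneric("rampDuration"))
#' @rdname accessors
#' @export
setGeneric("holdDuration", function(x) standardGeneric("holdDuration"))
#' @rdname accessors
#' @export
setGeneric("rampVoltages", function(x) standardGeneric("rampVoltages"))
#' @rdname accessors
#' @export
setGeneric("concentration", function(x) standardGeneric("concentration"))
#' @rdname accessors
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))
#' @rdname accessors
#' @export
setGeneric("esDa", function(x) standardGeneric("esDa"))
#' @rdname accessors
#' @export
setGeneric("tauSeconds", function(x) standardGeneric("tauSeconds"))
#' @rdname accessors
#' @export
setGeneric("calibrationFactor", function(x) standardGeneric("calibrationFactor"))

#' Accessors for fscv objects
#'
#' Small extraction helpers: `scans()` returns the scans-by-samples current
#' matrix of a [ScanStream-class]; `scanTimes()` its scan onset times;
#' `waveform()`, `gain()` and `channelId()` its acquisition metadata;
#' `rampDuration()` and `holdDuration()` the sweep and hold durations
#' (seconds) of a [RampWaveform-class]; `rampVoltages()` the sampled voltage
#' sequence of one sweep; `concentration()` and `qValues()` the nanomolar
#' trace and residuals of a [ConcentrationTrace-class]; `esDa()` and
#' `tauSeconds()` the release and clearance estimates of a
#' [KineticsResult-class]; `calibrationFactor()` the sensitivity (nA/uM) of a
#' [CalibrationCurve-class] or [ConcentrationTrace-class].
#'
#' @param x an fscv S4 object.
#' @return the corresponding slot value (see above).
#' @name accessors
NULL

#' @rdname accessors
setMethod("scans", "ScanStream", function(x) x@scans)
#' @rdname accessors
setMethod("scanTimes", "ScanStream", function(x) x@scanTimes)
#' @rdname accessors
setMethod("waveform", "ScanStream", function(x) x@waveform)
#' @rdname accessors
setMethod("gain", "ScanStream", function(x) x@gain)
#' @rdname accessors
setMethod("channelId", "ScanStream", function(x) x@channelId)
#' @rdname accessors
setMethod("channelId", "ConcentrationTrace", function(x) x@channelId)
#' @rdname accessors
setMethod("channelId", "KineticsResult", function(x) x@channelId)

#' @rdname accessors
setMethod("rampDuration", "RampWaveform", function(x)
  2 * (x@vPeak - x@vHold) / x@scanRate)
#' @rdname accessors
setMethod("holdDuration", "RampWaveform", function(x)
  1 / x@repetitionRate - rampDuration(x))

#' @rdname accessors
setMethod("rampVoltages", "RampWaveform", function(x) {
  # sample i covers [i, i+1)/n of the sweep; the apex lands exactly on the
  # half-scan sample and the point after the last sample is back at vHold
  n <- x@samplesPerScan
  frac <- seq(0L, n - 1L) / n
  x@vHold + (x@vPeak - x@vHold) * (1 - abs(2 * frac - 1))
})

#' @rdname accessors
setMethod("concentration", "ConcentrationTrace", function(x) x@concentration)
#' @rdname accessors
setMethod("qValues", "ConcentrationTrace", function(x) x@q)
#' @rdname accessors
setMethod("calibrationFactor", "ConcentrationTrace", function(x)
  x@calibrationFactor)
#' @rdname accessors
setMethod("calibrationFactor", "CalibrationCurve", function(x) x@factor)
#' @rdname accessors
setMethod("esDa", "KineticsResult", function(x) x@esDa)
#' @rdname accessors
setMethod("tauSeconds", "KineticsResult", function(x) x@tau)

setMethod("show", "RampWaveform", function(object) {
  cat(sprintf(
    "RampWaveform: %.2f -> %.2f -> %.2f V at %g V/s (%g samples)\n",
    object@vHold, object@vPeak, object@vHold, object@scanRate,
    object@samplesPerScan))
  cat(sprintf("  ramp %.3g ms, hold %.3g ms, repetition %g Hz\n",
              1e3 * rampDuration(object), 1e3 * holdDuration(object),
              object@repetitionRate))
})

setMethod("show", "ScanStream", function(object) {
  cat(sprintf(
    "ScanStream: channel %d, %d scans x %d samples (%.1f s at %g Hz)\n",
    object@channelId, nrow(object@scans), ncol(object@scans),
    nrow(object@scans) / object@waveform@repetitionRate,
    object@waveform@repetitionRate))
  if (length(object@meta$filters))
    cat("  filters:", paste(object@meta$filters, collapse = ", "), "\n")
})

setMethod("show", "StimEvent", function(object) {
  cat(sprintf("StimEvent: %d pulses at %g Hz, %g uA, onset %g s\n",
              object@pulseCount, object@frequency, object@amplitude,
              object@onsetTime))
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve: factor %.4g nA/uM (rms residual %.3g nA)\n",
              object@factor, object@fitResidual))
  cat("  ", paste(sprintf("%g uM: %.3g nA", object@concentrations,
                          object@meanCurrents), collapse = "; "), "\n")
})

setMethod("show", "TrainingSet", function(object) {
  tab <- table(object@analyte)
  cat(sprintf("TrainingSet: %d references x %d potential steps (%s)\n",
              nrow(object@spectra), ncol(object@spectra),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
})

setMethod("show", "PCRModel", function(object) {
  cat(sprintf(
    "PCRModel: k = %d components (%.2f%% variance), sensitivity %.4g nA/uM\n",
    object@k, 100 * object@varianceExplained, object@sensitivity))
  cat(sprintf("  Q threshold %.4g nA^2\n", object@qThreshold))
})

setMethod("show", "ConcentrationTrace", function(object) {
  cat(sprintf(
    "ConcentrationTrace: channel %d, %d scans, %.1f-%.1f s\n",
    object@channelId, length(object@time),
    min(object@time), max(object@time)))
  cat(sprintf("  [DA] range %.1f to %.1f nM; %d scan(s) Q-flagged\n",
              min(object@concentration), max(object@concentration),
              sum(object@flagged)))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "KineticsResult", function(object) {
  cat(sprintf("KineticsResult: channel %d\n", object@channelId))
  cat(sprintf("  ES DA %.1f nM (baseline %.1f, peak %.1f at %.1f s)\n",
              object@esDa, object@baseline, object@peak, object@peakTime))
  if (is.finite(object@tau))
    cat(sprintf("  tau %.3g s (R2 %.3f)\n", object@tau, object@tauR2))
  else cat("  tau: not fitted\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d channels, true ES DA %.1f nM, tau %g s, seed %d\n",
    length(object@sensitivity), max(c(object@esDa, 0)), object@tau,
    object@seed))
})
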
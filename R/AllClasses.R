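#' @import methods
NULL

#' RampWaveform: the applied triangular voltage waveform
#'
#' Describes the triangular potential sweep applied to each carbon-fiber
#' electrode: a linear ramp from the holding potential `vHold` up to `vPeak`
#' and symmetrically back, traversed at `scanRate` volts/second, digitized at
#' `samplesPerScan` points, and repeated at `repetitionRate` hertz with the
#' electrode parked at `vHold` between sweeps.
#'
#' At the defaults (-0.4 to +1.3 V at 400 V/s) the sweep lasts 8.5 ms and the
#' hold period at 10 Hz repetition is 91.5 ms.
#'
#' @slot vHold holding (start/end) potential, volts.
#' @slot vPeak apex potential, volts; must exceed `vHold`.
#' @slot scanRate sweep rate, volts/second.
#' @slot samplesPerScan number of digitized points per sweep.
#' @slot repetitionRate sweep repetition rate, hertz.
#'
#' @seealso [buildRamp()], [rampDuration()], [holdDuration()], [rampVoltages()]
#' @export
setClass("RampWaveform",
  slots = c(
    vHold = "numeric",
    vPeak = "numeric",
    scanRate = "numeric",
    samplesPerScan = "integer",
    repetitionRate = "numeric"
  )
)

setValidity("RampWaveform", function(object) {
  msgs <- character(0)
  for (s in c("vHold", "vPeak", "scanRate", "repetitionRate")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msgs <- c(msgs, sprintf("'%s' must be a finite scalar", s))
  }
  if (length(msgs) == 0L) {
    if (object@vPeak <= object@vHold)
      msgs <- c(msgs, "vPeak must exceed vHold")
    if (object@scanRate <= 0)
      msgs <- c(msgs, "scanRate must be positive")
    if (object@samplesPerScan < 2L)
      msgs <- c(msgs, "samplesPerScan must be at least 2")
    if (object@repetitionRate <= 0)
      msgs <- c(msgs, "repetitionRate must be positive")
    if (object@vPeak > object@vHold && object@scanRate > 0) {
      ramp <- 2 * (object@vPeak - object@vHold) / object@scanRate
      if (1 / object@repetitionRate < ramp - 1e-12)
        msgs <- c(msgs, sprintf(
          "repetition period (%.4g s) is shorter than the ramp duration (%.4g s)",
          1 / object@repetitionRate, ramp))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' ScanStream: one channel's sequence of voltammogram scans
#'
#' Raw or preprocessed current data for one electrode channel: a matrix with
#' one row per scan (acquired at `waveform@repetitionRate` hertz) and one
#' column per within-scan sample (`waveform@samplesPerScan` points spanning
#' the voltage ramp). Currents are in nanoamps.
#'
#' @slot channelId 0-based channel index (0-15 on the 16-channel array).
#' @slot scans numeric matrix, scans x samples, nanoamps.
#' @slot scanTimes scan onset times in seconds from recording start.
#' @slot waveform the [RampWaveform-class] in force during acquisition.
#' @slot gain transimpedance gain, nanoamps per volt (200 at the default
#'   4.99 MOhm feedback resistor).
#' @slot segmentLength on-disk segment length, seconds (30 by default).
#' @slot meta list of provenance fields (e.g. applied filters).
#'
#' @seealso [readRaw()], [writeRaw()], [lowpassScanFilter()],
#'   [highpassDriftFilter()]
#' @export
setClass("ScanStream",
  slots = c(
    channelId = "integer",
    scans = "matrix",
    scanTimes = "numeric",
    waveform = "RampWaveform",
    gain = "numeric",
    segmentLength = "numeric",
    meta = "list"
  )
)

setValidity("ScanStream", function(object) {
  msgs <- character(0)
  if (length(object@channelId) != 1L || object@channelId < 0L)
    msgs <- c(msgs, "channelId must be a single nonnegative integer")
  if (ncol(object@scans) != object@waveform@samplesPerScan)
    msgs <- c(msgs, sprintf(
      "each scan must have exactly %d samples (got %d)",
      object@waveform@samplesPerScan, ncol(object@scans)))
  if (nrow(object@scans) != length(object@scanTimes))
    msgs <- c(msgs, "scanTimes length must equal the number of scans")
  if (length(object@scanTimes) > 1L) {
    dt <- diff(object@scanTimes)
    expected <- 1 / object@waveform@repetitionRate
    if (any(dt <= 0))
      msgs <- c(msgs, "scanTimes must be strictly increasing")
    else if (any(abs(dt - expected) > 1e-6 * max(1, expected)))
      msgs <- c(msgs, sprintf(
        "scanTimes spacing must be 1/repetitionRate = %.6g s", expected))
  }
  if (length(object@gain) != 1L || object@gain <= 0)
    msgs <- c(msgs, "gain must be a positive scalar")
  if (length(object@segmentLength) != 1L || object@segmentLength <= 0)
    msgs <- c(msgs, "segmentLength must be a positive scalar")
  if (length(msgs)) msgs else TRUE
})

#' StimEvent: an electrical stimulation train
#'
#' A train of `pulseCount` pulses at `frequency` hertz delivered to the
#' stimulating electrode starting `onsetTime` seconds into the recording.
#' Trigger pulses are issued during the waveform hold periods so they do not
#' collide with the voltage ramp.
#'
#' @slot onsetTime seconds from recording start (5 s by convention for a
#'   30 s stimulation recording).
#' @slot frequency pulse frequency, hertz (30 or 60 in the source protocols).
#' @slot pulseCount number of pulses (15, 30 or 60).
#' @slot amplitude stimulation current, microamps.
#'
#' @export
setClass("StimEvent",
  slots = c(
    onsetTime = "numeric",
    frequency = "numeric",
    pulseCount = "integer",
    amplitude = "numeric"
  )
)

setValidity("StimEvent", function(object) {
  msgs <- character(0)
  if (object@onsetTime < 0) msgs <- c(msgs, "onsetTime must be nonnegative")
  if (object@frequency <= 0) msgs <- c(msgs, "frequency must be positive")
  if (object@pulseCount < 1L) msgs <- c(msgs, "pulseCount must be at least 1")
  if (object@amplitude <= 0) msgs <- c(msgs, "amplitude must be positive")
  if (length(msgs)) msgs else TRUE
})

#' CalibrationCurve: flow-cell dopamine sensitivity of a device
#'
#' Per-concentration mean currents from flow-cell boluses and the fitted
#' sensitivity `factor` (nanoamps per micromolar dopamine), a through-origin
#' least-squares slope by default.
#'
#' @slot concentrations bolus concentrations, micromolar.
#' @slot meanCurrents mean plateau current per concentration, nanoamps.
#' @slot factor fitted sensitivity, nanoamps per micromolar; positive.
#' @slot fitResidual root-mean-square residual of the fit, nanoamps.
#'
#' @seealso [fitCalibrationCurve()], [applyCalibration()]
#' @export
setClass("CalibrationCurve",
  slots = c(
    concentrations = "numeric",
    meanCurrents = "numeric",
    factor = "numeric",
    fitResidual = "numeric"
  )
)

setValidity("CalibrationCurve", function(object) {
  msgs <- character(0)
  if (length(object@concentrations) != length(object@meanCurrents))
    msgs <- c(msgs, "concentrations and meanCurrents must have equal length")
  if (length(object@factor) != 1L || !is.finite(object@factor) ||
      object@factor <= 0)
    msgs <- c(msgs, "factor must be a positive scalar")
  if (length(object@concentrations) > 1L) {
    o <- order(object@concentrations)
    cur <- object@meanCurrents[o]
    tol <- 0.05 * max(abs(cur), 1e-12)  # small inversions from noise tolerated
    if (any(diff(cur) < -tol))
      msgs <- c(msgs, "meanCurrents must be nondecreasing in concentration")
  }
  if (length(msgs)) msgs else TRUE
})

#' TrainingSet: labeled reference voltammograms for chemometrics
#'
#' Background-subtracted reference voltammograms with known analyte identity
#' and magnitude, used to train the principal component regression model. The
#' canonical composition is five dopamine, three acidic-pH and two basic-pH
#' references.
#'
#' @slot spectra matrix, references x potential steps, nanoamps.
#' @slot analyte character vector: `"DA"`, `"acidic_pH"` or `"basic_pH"`.
#' @slot magnitude known magnitude per reference: micromolar for DA rows,
#'   (signed) pH units for pH rows.
#'
#' @seealso [trainingSet()], [defaultTrainingSet()], [fitPCR()]
#' @export
setClass("TrainingSet",
  slots = c(
    spectra = "matrix",
    analyte = "character",
    magnitude = "numeric"
  )
)

setValidity("TrainingSet", function(object) {
  msgs <- character(0)
  n <- nrow(object@spectra)
  if (length(object@analyte) != n || length(object@magnitude) != n)
    msgs <- c(msgs, "analyte and magnitude must have one entry per spectrum")
  bad <- setdiff(unique(object@analyte), c("DA", "acidic_pH", "basic_pH"))
  if (length(bad))
    msgs <- c(msgs, paste0("unknown analyte label(s): ",
                           paste(bad, collapse = ", ")))
  if (!any(object@analyte == "DA"))
    msgs <- c(msgs, "training set must contain at least one DA reference")
  if (length(msgs)) msgs else TRUE
})

#' PCRModel: trained principal component regression model
#'
#' Retained principal directions of the training spectra plus a least-squares
#' map from component scores to analyte magnitudes. The DA output is in
#' DA-equivalent current (nanoamps) so that conversion to concentration goes
#' through the electrode calibration factor, matching the measurement chain.
#'
#' @slot meanSpectrum training-set mean voltammogram (diagnostic; prediction
#'   is through the origin because references are background-subtracted).
#' @slot components matrix, potential steps x k, orthonormal retained
#'   principal directions.
#' @slot k number of retained components.
#' @slot regressionMap k x 2 matrix mapping scores to `(da_nA, ph)` outputs.
#' @slot sensitivity training-electrode DA sensitivity, nanoamps/micromolar.
#' @slot qThreshold residual (Q) flagging threshold, squared nanoamps.
#' @slot varianceExplained cumulative variance captured by the k components.
#'
#' @seealso [fitPCR()], [predictDA()]
#' @export
setClass("PCRModel",
  slots = c(
    meanSpectrum = "numeric",
    components = "matrix",
    k = "integer",
    regressionMap = "matrix",
    sensitivity = "numeric",
    qThreshold = "numeric",
    varianceExplained = "numeric"
  )
)

setValidity("PCRModel", function(object) {
  msgs <- character(0)
  if (ncol(object@components) != object@k)
    msgs <- c(msgs, "components must have k columns")
  if (nrow(object@regressionMap) != object@k)
    msgs <- c(msgs, "regressionMap must have k rows")
  if (object@sensitivity <= 0)
    msgs <- c(msgs, "sensitivity must be positive")
  if (length(msgs)) msgs else TRUE
})

#' ConcentrationTrace: per-scan dopamine concentration for one channel
#'
#' The chemometric DA estimate converted to nanomolar with an electrode
#' calibration factor, one value per scan, with per-scan residual (Q) values
#' and flags.
#'
#' @slot channelId 0-based channel index.
#' @slot time scan times, seconds.
#' @slot concentration dopamine concentration, nanomolar.
#' @slot q per-scan chemometric residual, squared nanoamps.
#' @slot flagged logical per scan: residual exceeded the Q threshold.
#' @slot flags trace-level flag strings.
#' @slot calibrationFactor nanoamps per micromolar used for conversion.
#'
#' @seealso [applyCalibration()], [esDaRelease()], [fitTau()]
#' @export
setClass("ConcentrationTrace",
  slots = c(
    channelId = "integer",
    time = "numeric",
    concentration = "numeric",
    q = "numeric",
    flagged = "logical",
    flags = "character",
    calibrationFactor = "numeric"
  )
)

setValidity("ConcentrationTrace", function(object) {
  msgs <- character(0)
  n <- length(object@time)
  if (length(object@concentration) != n)
    msgs <- c(msgs, "concentration and time must have equal length")
  if (length(object@q) != n && length(object@q) != 0L)
    msgs <- c(msgs, "q must be empty or one value per scan")
  if (length(object@flagged) != n && length(object@flagged) != 0L)
    msgs <- c(msgs, "flagged must be empty or one value per scan")
  if (n > 1L && any(diff(object@time) <= 0))
    msgs <- c(msgs, "time must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' KineticsResult: stimulated release and clearance for one event
#'
#' ES DA (electrically stimulated dopamine release) is the peak concentration
#' within 10 s of stimulation onset minus the pre-stimulation baseline. Tau is
#' the time constant (seconds) of a single-exponential fit to the post-peak
#' decay; larger Tau means slower reuptake.
#'
#' @slot channelId 0-based channel index.
#' @slot esDa stimulated release, nanomolar (peak - baseline).
#' @slot baseline pre-stimulation baseline, nanomolar.
#' @slot peak peak concentration within the 10 s window, nanomolar.
#' @slot peakTime time of the peak, seconds.
#' @slot tau clearance time constant, seconds (NA if the fit failed).
#' @slot tauR2 goodness of fit of the exponential decay.
#' @slot flags character flags (`"no_response"`, `"fit_failed"`, ...).
#'
#' @seealso [esDaRelease()], [fitTau()], [quantifyKinetics()]
#' @export
setClass("KineticsResult",
  slots = c(
    channelId = "integer",
    esDa = "numeric",
    baseline = "numeric",
    peak = "numeric",
    peakTime = "numeric",
    tau = "numeric",
    tauR2 = "numeric",
    flags = "character"
  )
)

#' GroundTruth: generator-side truth for a synthetic recording
#'
#' Everything the synthetic recording generator knows that the pipeline has
#' to recover: the true concentration time course, per-channel sensitivities,
#' expected per-channel ES DA under the cohort calibration factor, the decay
#' time constant, the dropout schedule and the noise level.
#'
#' @slot time trace times, seconds.
#' @slot concentration true DA concentration, nanomolar.
#' @slot esDa expected measured ES DA per channel, nanomolar.
#' @slot tau true clearance time constant, seconds.
#' @slot sensitivity per-channel sensitivity, nanoamps/micromolar.
#' @slot factor cohort calibration factor used for read-back, nA/uM.
#' @slot dropout 0-based indices of silenced channels.
#' @slot noiseSd additive current noise SD, nanoamps.
#' @slot seed generator seed.
#' @slot config the generator configuration list.
#'
#' @seealso [generateRecording()]
#' @export
setClass("GroundTruth",
  slots = c(
    time = "numeric",
    concentration = "numeric",
    esDa = "numeric",
    tau = "numeric",
    sensitivity = "numeric",
    factor = "numeric",
    dropout = "integer",
    noiseSd = "numeric",
    seed = "integer",
    config = "list"
  )
)
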
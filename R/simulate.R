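# Synthetic multichannel FSCV recordings with ground truth. The generator
# emulates the regimes of chronic striatal recordings: stimulated DA
# transients of order 10^2-10^3 nM riding on a large charging-current
# background with slow drift, cross-fiber sensitivity heterogeneity tuned to
# a target coefficient of variation, additive white current noise, and
# channel dropout. Everything is deterministic given the seed.

#' Simulate stimulated dopamine kinetics
#'
#' First-order release/reuptake dynamics `dc/dt = r(t) - c/tau`, where
#' `r(t)` delivers `releasePerPulse` nanomolar instantaneously at each
#' stimulus pulse. The solution is the superposition of exponentially
#' decaying impulses, evaluated exactly on the sample grid, so a single
#' pulse yields a pure `exp(-t/tau)` decay.
#'
#' @param stim a [StimEvent-class] (or `NULL` for a stimulus-free trace).
#' @param releasePerPulse nanomolar released per pulse.
#' @param tau clearance time constant, seconds.
#' @param dt sample interval, seconds (0.1 s matches 10 Hz scanning).
#' @param duration trace length, seconds.
#' @return data.frame with `time` (s) and `conc_nM`.
#' @export
simulateKinetics <- function(stim, releasePerPulse = 15, tau = 2,
                             dt = 0.1, duration = 30) {
  stopifnot(releasePerPulse >= 0, tau > 0, dt > 0, duration > dt)
  t <- seq(0, duration - dt, by = dt)
  conc <- numeric(length(t))
  if (!is.null(stim) && stim@pulseCount >= 1L && releasePerPulse > 0) {
    tp <- stim@onsetTime + (seq_len(stim@pulseCount) - 1L) / stim@frequency
    tp <- tp[tp <= max(t)]
    for (p in tp) {
      after <- t >= p
      conc[after] <- conc[after] + releasePerPulse * exp(-(t[after] - p) / tau)
    }
  }
  data.frame(time = t, conc_nM = conc)
}

#' Voltammogram feature templates
#'
#' Unit-amplitude analyte signatures along the voltage ramp: the DA template
#' has a Gaussian oxidation peak where the rising limb crosses
#' `oxPotential` and a reduction trough (half amplitude) where the falling
#' limb crosses `redPotential`; the two pH templates are broader features at
#' distinct potentials. All are normalized so the DA oxidation peak is 1, and
#' their shapes are parameterized conventions, not claims about any
#' particular device.
#'
#' @param waveform a [RampWaveform-class].
#' @param oxPotential DA oxidation potential, volts (rising limb).
#' @param redPotential DA reduction potential, volts (falling limb).
#' @param widthFraction Gaussian width as a fraction of the scan length.
#' @return list with numeric templates `da`, `phAcid`, `phBasic`, the
#'   `background` shape (unit charging-current square profile), and
#'   `oxIndex`, the sample index of the DA oxidation peak.
#' @export
voltammogramTemplates <- function(waveform = buildRamp(), oxPotential = 0.6,
                                  redPotential = -0.2,
                                  widthFraction = 0.04) {
  v <- rampVoltages(waveform)
  n <- length(v)
  half <- ceiling(n / 2)
  rising <- seq_len(half)
  falling <- (half + 1L):n
  iOx <- rising[which.min(abs(v[rising] - oxPotential))]
  iRed <- falling[which.min(abs(v[falling] - redPotential))]
  w <- widthFraction * n
  i <- seq_len(n)
  g <- function(center, width) exp(-((i - center)^2) / (2 * width^2))
  da <- g(iOx, w) - 0.5 * g(iRed, w)
  da <- da / max(da)
  phAcid <- g(half, 3 * w) - 0.3 * g(round(0.15 * n), 2 * w)
  phAcid <- phAcid / max(abs(phAcid))
  phBasic <- -g(round(0.8 * n), 2.5 * w) + 0.4 * g(round(0.3 * n), 2 * w)
  phBasic <- phBasic / max(abs(phBasic))
  background <- tanh((rising[half] - abs(i - half)) / (0.02 * n))
  background <- c(rep(1, half), rep(-1, n - half)) *
    (1 - g(half, 0.5 * w)) * (1 - g(1, 0.5 * w)) * (1 - g(n, 0.5 * w))
  list(da = da, phAcid = phAcid, phBasic = phBasic,
       background = background, oxIndex = iOx)
}

#' Synthesize a single voltammogram scan
#'
#' `scan = background + (daNM/1000) * sensitivity * da_template +
#' phShift * pH_template`, with the acidic template used for negative pH
#' shifts and the basic template for positive ones.
#'
#' @param daNM dopamine concentration, nanomolar.
#' @param phShift signed pH shift (pH units; 0 for none).
#' @param waveform a [RampWaveform-class].
#' @param templates output of [voltammogramTemplates()] for that waveform.
#' @param sensitivity electrode sensitivity, nanoamps per micromolar.
#' @param background background current vector, nanoamps (0 for a
#'   background-subtracted scan).
#' @param phAmplitude current per unit pH shift, nanoamps.
#' @return numeric scan of `samplesPerScan` nanoamp values.
#' @export
synthesizeScan <- function(daNM, phShift = 0, waveform = buildRamp(),
                           templates = voltammogramTemplates(waveform),
                           sensitivity = 10, background = 0,
                           phAmplitude = 30) {
  n <- waveform@samplesPerScan
  if (length(templates$da) != n)
    stop("template length does not match waveform samplesPerScan")
  phTemplate <- if (phShift < 0) templates$phAcid else templates$phBasic
  scan <- background + (daNM / 1000) * sensitivity * templates$da +
    abs(phShift) * phAmplitude * phTemplate
  as.numeric(scan)
}

#' Canonical synthetic training set (5 DA, 3 acidic, 2 basic)
#'
#' Background-subtracted reference voltammograms built from the analyte
#' templates at known magnitudes, passed through the same per-scan low-pass
#' filter as the measurement pipeline so that trained directions match
#' preprocessed data.
#'
#' @param waveform a [RampWaveform-class].
#' @param templates output of [voltammogramTemplates()].
#' @param sensitivity reference electrode sensitivity, nA/uM.
#' @param daConc DA reference concentrations, micromolar (5 values).
#' @param acidShift acidic pH reference shifts (negative, 3 values).
#' @param basicShift basic pH reference shifts (positive, 2 values).
#' @param phAmplitude current per unit pH shift, nanoamps.
#' @param lowpass apply the pipeline's per-scan low-pass to the references.
#' @return a [TrainingSet-class].
#' @export
defaultTrainingSet <- function(waveform = buildRamp(),
                               templates = voltammogramTemplates(waveform),
                               sensitivity = 10,
                               daConc = c(0.25, 0.5, 1, 2, 4),
                               acidShift = c(-0.05, -0.1, -0.2),
                               basicShift = c(0.1, 0.2),
                               phAmplitude = 30,
                               lowpass = TRUE) {
  rows <- c(
    lapply(daConc, function(cc) synthesizeScan(
      cc * 1000, 0, waveform, templates, sensitivity, 0, phAmplitude)),
    lapply(acidShift, function(sh) synthesizeScan(
      0, sh, waveform, templates, sensitivity, 0, phAmplitude)),
    lapply(basicShift, function(sh) synthesizeScan(
      0, sh, waveform, templates, sensitivity, 0, phAmplitude))
  )
  X <- do.call(rbind, rows)
  if (lowpass) {
    ss <- scanStream(X, waveform = waveform,
                     scanTimes = (seq_len(nrow(X)) - 1L) /
                       waveform@repetitionRate)
    X <- scans(lowpassScanFilter(ss))
  }
  trainingSet(X,
              analyte = c(rep("DA", length(daConc)),
                          rep("acidic_pH", length(acidShift)),
                          rep("basic_pH", length(basicShift))),
              magnitude = c(daConc, acidShift, basicShift))
}

#' Generator configuration
#'
#' Defaults describe a standard 30 s stimulation recording on the 16-channel
#' array: 60 Hz 30-pulse train 5 s in, ~400 nM ES DA, tau 2 s, mean
#' sensitivity 10 nA/uM with cross-fiber coefficient of variation 0.27,
#' a several-hundred-nA charging background with exponential settling plus a
#' slow random walk, and 0.3 nA white current noise.
#'
#' @param nChannels number of electrode channels.
#' @param duration recording length, seconds.
#' @param waveform a [RampWaveform-class].
#' @param stim a [StimEvent-class] or `NULL` for a baseline recording.
#' @param releasePerPulse nanomolar per pulse.
#' @param tau clearance time constant, seconds.
#' @param sensitivityMean mean electrode sensitivity, nA/uM.
#' @param sensitivityCV cross-channel coefficient of variation of
#'   sensitivity (log-normal; 0 for identical channels).
#' @param backgroundAmp charging-current background amplitude, nanoamps.
#' @param chargingAmp,chargingTau exponential background settling amplitude
#'   (nA) and time constant (s).
#' @param driftStep per-scan SD of the slow random-walk drift, nanoamps.
#' @param noiseSd additive white current noise SD per sample, nanoamps.
#' @param phAmplitude current per unit pH shift, nanoamps.
#' @param dropout 0-based channel ids rendered silent (noise only).
#' @param segmentLength on-disk segment length, seconds.
#' @param gain transimpedance gain, nA/V.
#' @return a config list for [generateRecording()].
#' @export
simConfig <- function(nChannels = 16L, duration = 30,
                      waveform = buildRamp(),
                      stim = stimEvent(),
                      releasePerPulse = 15, tau = 2,
                      sensitivityMean = 10, sensitivityCV = 0.27,
                      backgroundAmp = 400, chargingAmp = 2,
                      chargingTau = 60, driftStep = 0.01,
                      noiseSd = 0.3, phAmplitude = 30,
                      dropout = integer(0), segmentLength = 30,
                      gain = 200) {
  list(nChannels = as.integer(nChannels), duration = duration,
       waveform = waveform, stim = stim,
       releasePerPulse = releasePerPulse, tau = tau,
       sensitivityMean = sensitivityMean, sensitivityCV = sensitivityCV,
       backgroundAmp = backgroundAmp, chargingAmp = chargingAmp,
       chargingTau = chargingTau, driftStep = driftStep,
       noiseSd = noiseSd, phAmplitude = phAmplitude,
       dropout = as.integer(dropout), segmentLength = segmentLength,
       gain = gain)
}

.truthKinetics <- function(cfg) {
  dt <- 1 / cfg$waveform@repetitionRate
  kin <- simulateKinetics(cfg$stim, cfg$releasePerPulse, cfg$tau,
                          dt = dt, duration = cfg$duration)
  if (is.null(cfg$stim) || cfg$releasePerPulse == 0)
    return(list(kin = kin, es = 0))
  onset <- cfg$stim@onsetTime
  inWin <- kin$time > onset & kin$time <= onset + 10
  list(kin = kin, es = max(kin$conc_nM[inWin]))
}

#' Generate a synthetic multichannel recording with ground truth
#'
#' Draws per-channel sensitivities (log-normal with the configured
#' cross-channel CV), builds each channel's scan stream as background +
#' charging/drift + DA transient + white noise, optionally writes the raw
#' dialect to disk, and returns the [GroundTruth-class]. The per-channel
#' "expected measured" ES DA in the truth is the true released peak scaled
#' by `sensitivity_ch / cohort factor`, where the cohort calibration factor
#' is the mean sensitivity -- this is what a pipeline using a single
#' per-device calibration factor should recover, and what makes the
#' cross-channel ES DA dispersion match the sensitivity CV.
#'
#' @param config a [simConfig()] list.
#' @param seed integer seed; the same seed reproduces the recording
#'   bit-for-bit.
#' @param dir optional output directory for the raw dialect (plus
#'   `truth.json`).
#' @param returnStreams return in-memory [ScanStream-class] objects.
#' @return list with `truth` ([GroundTruth-class]), `streams` (list or
#'   `NULL`), `dir`.
#' @export
generateRecording <- function(config = simConfig(), seed = 1L, dir = NULL,
                              returnStreams = TRUE) {
  cfg <- config
  set.seed(as.integer(seed))
  wf <- cfg$waveform
  tmpl <- voltammogramTemplates(wf)
  tk <- .truthKinetics(cfg)
  nScans <- nrow(tk$kin)
  n <- wf@samplesPerScan
  scanT <- tk$kin$time

  sdlog <- sqrt(log(1 + cfg$sensitivityCV^2))
  sens <- cfg$sensitivityMean *
    stats::rlnorm(cfg$nChannels, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  factor <- cfg$sensitivityMean

  bg <- cfg$backgroundAmp * tmpl$background
  streams <- vector("list", cfg$nChannels)
  for (ch in seq_len(cfg$nChannels) - 1L) {
    drift <- cfg$chargingAmp * exp(-scanT / cfg$chargingTau) +
      cumsum(stats::rnorm(nScans, 0, cfg$driftStep))
    da <- if (ch %in% cfg$dropout) numeric(nScans) else tk$kin$conc_nM
    m <- matrix(bg, nrow = nScans, ncol = n, byrow = TRUE)
    m <- m + drift +
      outer((da / 1000) * sens[ch + 1L], tmpl$da)
    if (cfg$noiseSd > 0)
      m <- m + matrix(stats::rnorm(nScans * n, 0, cfg$noiseSd),
                      nrow = nScans)
    streams[[ch + 1L]] <- scanStream(m, channelId = ch, waveform = wf,
                                     gain = cfg$gain,
                                     segmentLength = cfg$segmentLength,
                                     scanTimes = scanT)
  }

  esCh <- tk$es * sens / factor
  esCh[cfg$dropout + 1L] <- 0
  truth <- new("GroundTruth", time = scanT,
               concentration = tk$kin$conc_nM, esDa = esCh,
               tau = cfg$tau, sensitivity = sens, factor = factor,
               dropout = cfg$dropout, noiseSd = cfg$noiseSd,
               seed = as.integer(seed),
               config = cfg[setdiff(names(cfg), c("waveform", "stim"))])

  if (!is.null(dir)) {
    writeRaw(streams, dir)
    jsonlite::write_json(
      list(seed = truth@seed, tau = truth@tau, factor = truth@factor,
           esDa = truth@esDa, sensitivity = truth@sensitivity,
           dropout = truth@dropout, noiseSd = truth@noiseSd,
           time = truth@time, concentration = truth@concentration),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  list(truth = truth, streams = if (returnStreams) streams else NULL,
       dir = dir)
}

#' Read back a serialized ground truth
#'
#' @param dir recording directory containing `truth.json`.
#' @return a [GroundTruth-class].
#' @export
readGroundTruth <- function(dir) {
  x <- jsonlite::read_json(file.path(dir, "truth.json"),
                           simplifyVector = TRUE)
  new("GroundTruth", time = x$time, concentration = x$concentration,
      esDa = x$esDa, tau = x$tau, sensitivity = x$sensitivity,
      factor = x$factor, dropout = as.integer(x$dropout),
      noiseSd = x$noiseSd, seed = as.integer(x$seed), config = list())
}
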
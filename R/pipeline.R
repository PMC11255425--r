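# End-to-end processing of one multichannel stimulation recording: filters,
# chemometrics, calibration, kinetics, then the below-threshold and +-2 SD
# channel QC rules.

#' Per-scan detected current at the DA oxidation potential
#'
#' The scan-by-scan current at the sample index where the rising limb
#' crosses the DA oxidation potential -- the time series practitioners watch
#' during cycling to judge electrode stability.
#'
#' @param stream a (typically preprocessed) [ScanStream-class].
#' @param oxIndex sample index; defaults to the oxidation-peak index of the
#'   waveform's DA template.
#' @return numeric vector, one current (nA) per scan.
#' @export
detectedCurrent <- function(stream, oxIndex = NULL) {
  if (is.null(oxIndex))
    oxIndex <- voltammogramTemplates(waveform(stream))$oxIndex
  scans(stream)[, oxIndex]
}

#' Process one multichannel recording
#'
#' For every channel: two-stage preprocessing, chemometric DA prediction
#' with a baseline-derived residual threshold, calibration to nanomolar, and
#' ES DA / Tau quantification. Channels whose ES DA is below
#' `noiseMultiple` times the baseline concentration SD are marked
#' `below_threshold` and excluded from the cross-channel outlier test; the
#' remaining ES DA values then pass through the single-pass +-`nSd` SD
#' outlier rule.
#'
#' @param streams list of [ScanStream-class] (e.g. from [readRaw()]) or a
#'   recording directory.
#' @param model a [PCRModel-class].
#' @param factor calibration factor (nA/uM) or [CalibrationCurve-class].
#' @param stim the [StimEvent-class] of the recording.
#' @param baselineWindow pre-stimulation baseline window, seconds.
#' @param noiseMultiple below-threshold rule multiplier (3 by default).
#' @param minEs absolute detection floor on ES DA, nanomolar; responses
#'   below it are below threshold regardless of the noise estimate.
#' @param nSd outlier rule width in standard deviations.
#' @param preprocess apply the filter stages (disable if `streams` are
#'   already preprocessed).
#' @return list with `results` (per-channel data.frame incl. `qc_status`),
#'   `traces` (list of [ConcentrationTrace-class]), `kinetics` (list of
#'   [KineticsResult-class]), `qc` (output of [removeOutlierChannels()]).
#' @export
processRecording <- function(streams, model, factor, stim,
                             baselineWindow = 2, noiseMultiple = 3,
                             minEs = 1, nSd = 2, preprocess = TRUE) {
  if (is.character(streams)) streams <- readRaw(streams)
  if (is(streams, "ScanStream")) streams <- list(streams)
  traces <- list()
  kin <- list()
  rows <- list()
  for (s in streams) {
    if (preprocess) s <- preprocessStream(s)
    pred <- predictDA(model, s)
    tIdx <- scanTimes(s) <= stim@onsetTime - 0.5
    # numerical floor: residuals far below the scan energy are round-off,
    # not chemistry, and must not trip the flag in near-noiseless data
    qFloor <- 1e-9 * stats::median(rowSums(scans(s)^2))
    qThr <- if (sum(tIdx) >= 10L)
      max(baselineQThreshold(pred$q[tIdx]), qFloor)
    else max(model@qThreshold, qFloor)
    pred$flagged <- pred$q > qThr
    tr <- applyCalibration(pred$da_nA, factor, scanTimes(s),
                           channelId = channelId(s), q = pred$q,
                           flagged = pred$flagged)
    k <- quantifyKinetics(tr, stim, baselineWindow = baselineWindow)
    noiseSd <- stats::sd(
      concentration(tr)[tr@time >= stim@onsetTime - baselineWindow &
                          tr@time <= stim@onsetTime])
    below <- k@esDa < noiseMultiple * noiseSd || k@esDa < minEs
    ch <- sprintf("ch%02d", channelId(s))
    traces[[ch]] <- tr
    kin[[ch]] <- k
    rows[[ch]] <- data.frame(
      channel = channelId(s), es_da_nM = k@esDa, baseline_nM = k@baseline,
      peak_nM = k@peak, tau_s = k@tau, r2 = k@tauR2,
      noise_sd_nM = noiseSd, below_threshold = below,
      flags = paste(k@flags, collapse = ";"))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  testable <- which(!res$below_threshold)
  vals <- rep(NA_real_, nrow(res))
  vals[testable] <- res$es_da_nM[testable]
  qc <- removeOutlierChannels(vals, nSd = nSd)
  res$qc_status <- ifelse(res$below_threshold, "below_threshold", "ok")
  res$qc_status[seq_len(nrow(res)) %in% qc$outliers] <- "outlier"
  list(results = res, traces = traces, kinetics = kin, qc = qc)
}

#' Pseudocolor plot of a scan stream
#'
#' The standard FSCV rendering: time on the x axis, applied potential
#' (unfolded scan sample index) on the y axis, current as color.
#'
#' @param stream a [ScanStream-class].
#' @param zlim color scale limits (symmetric about 0 by default).
#' @param main title.
#' @return invisibly, the current matrix that was drawn.
#' @export
plotPseudocolor <- function(stream, zlim = NULL, main = NULL) {
  m <- scans(stream)
  if (is.null(zlim)) {
    r <- max(abs(range(m)))
    zlim <- c(-r, r)
  }
  pal <- grDevices::colorRampPalette(
    c("#313695", "#4575b4", "#e0f3f8", "#ffffbf", "#fdae61", "#d73027"))
  if (is.null(main))
    main <- sprintf("channel %d", channelId(stream))
  graphics::image(x = scanTimes(stream),
                  y = seq_len(ncol(m)),
                  z = pmin(pmax(m, zlim[1]), zlim[2]),
                  zlim = zlim, col = pal(256),
                  xlab = "time (s)", ylab = "scan sample (potential)",
                  main = main, useRaster = TRUE)
  invisible(m)
}

#' Write a per-recording results table
#'
#' @param results the `results` data.frame from [processRecording()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
writeResultsTable <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
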
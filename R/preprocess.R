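# Two-stage preprocessing, both Butterworth IIR:
#   1. per-scan 4th-order 2 kHz low-pass along the within-scan axis
#      (within-scan sampling rate = samplesPerScan / rampDuration,
#      ~117.6 kHz at the defaults), removing non-biological noise;
#   2. per-potential-step 2nd-order 0.01 Hz high-pass across scans at the
#      repetition rate, applied zero-phase (forward-backward), removing the
#      slow background drift from the charging current.
# Filtering uses steady-state initial conditions scaled to the first sample,
# so a DC input maps exactly to its steady-state response (constant scans
# are annihilated by the high-pass stage), plus odd-reflection padding of
# 3 x order for the zero-phase pass.

# Single-pass IIR with zero initial state: FIR stage then recursion, both
# through stats::filter (C implementations).
.iirFilter <- function(b, a, x) {
  nb <- length(b)
  xp <- if (nb > 1L) c(numeric(nb - 1L), x) else x
  v <- stats::filter(xp, b, method = "convolution", sides = 1L)
  v <- as.numeric(v)
  if (nb > 1L) v <- v[-seq_len(nb - 1L)]
  if (length(a) > 1L)
    v <- as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
  v
}

# Steady-state initial conditions: response to x is the zero-state response
# to (x - x[1]) plus the steady-state response to the constant x[1].
.iirFilterSS <- function(b, a, x) {
  dc <- sum(b) / sum(a)
  .iirFilter(b, a, x - x[1L]) + x[1L] * dc
}

# Zero-phase forward-backward pass with odd-reflection padding.
.filtfilt <- function(b, a, x, padlen) {
  n <- length(x)
  if (n <= padlen)
    stop(sprintf(
      "series of length %d is shorter than the filter warm-up length (%d)",
      n, padlen + 1L))
  if (padlen > 0L) {
    front <- 2 * x[1L] - x[(padlen + 1L):2L]
    back <- 2 * x[n] - x[(n - 1L):(n - padlen)]
    x <- c(front, x, back)
  }
  y <- .iirFilterSS(b, a, x)
  y <- rev(.iirFilterSS(b, a, rev(y)))
  if (padlen > 0L) y <- y[(padlen + 1L):(padlen + n)]
  y
}

.requireStream <- function(stream) {
  if (!is(stream, "ScanStream")) stop("expected a ScanStream")
  validObject(stream)
}

#' Within-scan sampling rate of a waveform
#'
#' Samples per second along one voltage sweep:
#' `samplesPerScan / rampDuration` (about 117.6 kHz at the defaults).
#'
#' @param waveform a [RampWaveform-class].
#' @return sampling rate in hertz.
#' @export
withinScanRate <- function(waveform) {
  waveform@samplesPerScan / rampDuration(waveform)
}

#' Low-pass filter each voltammogram scan
#'
#' Applies a causal Butterworth low-pass (4th order, 2 kHz by default) to
#' every scan independently along the within-scan axis, leaving the output
#' shape unchanged. DC is passed with unit gain.
#'
#' @param stream a [ScanStream-class].
#' @param order filter order.
#' @param cutoffHz cutoff frequency, hertz; must be below the within-scan
#'   Nyquist frequency.
#' @return the filtered [ScanStream-class].
#' @export
lowpassScanFilter <- function(stream, order = 4L, cutoffHz = 2000) {
  .requireStream(stream)
  nyquist <- withinScanRate(waveform(stream)) / 2
  if (cutoffHz >= nyquist)
    stop(sprintf("cutoff %g Hz is not below the within-scan Nyquist %g Hz",
                 cutoffHz, nyquist))
  bf <- signal::butter(order, cutoffHz / nyquist, type = "low")
  m <- scans(stream)
  out <- t(apply(m, 1L, function(x) .iirFilterSS(bf$b, bf$a, x)))
  stream@scans <- out
  stream@meta$filters <- c(stream@meta$filters,
                           sprintf("lowpass(order=%d, cutoff=%gHz)",
                                   order, cutoffHz))
  stream
}

#' Zero-phase high-pass drift removal across scans
#'
#' For each of the potential steps, the time series across scans is filtered
#' forward and backward with a Butterworth high-pass (2nd order, 0.01 Hz by
#' default) at the scan repetition rate. The forward-backward pass has zero
#' group delay, so transients are not shifted in time; slow background drift
#' (charging-current relaxation, electrode drift) is removed. Edges are
#' handled by odd-reflection padding of three filter orders per end.
#'
#' @param stream a [ScanStream-class].
#' @param order filter order of the single pass (the zero-phase magnitude
#'   response is that order doubled).
#' @param cutoffHz high-pass cutoff, hertz.
#' @return the filtered [ScanStream-class].
#' @export
highpassDriftFilter <- function(stream, order = 2L, cutoffHz = 0.01) {
  .requireStream(stream)
  fs <- waveform(stream)@repetitionRate
  if (cutoffHz >= fs / 2)
    stop(sprintf("cutoff %g Hz is not below the scan-rate Nyquist %g Hz",
                 cutoffHz, fs / 2))
  padlen <- 3L * order
  if (nrow(scans(stream)) <= padlen)
    stop(sprintf("need more than %d scans for the zero-phase drift filter",
                 padlen))
  bf <- signal::butter(order, cutoffHz / (fs / 2), type = "high")
  m <- scans(stream)
  out <- apply(m, 2L, function(x) .filtfilt(bf$b, bf$a, x, padlen))
  stream@scans <- out
  stream@meta$filters <- c(stream@meta$filters,
                           sprintf("highpass(order=%d, cutoff=%gHz, zero-phase)",
                                   order, cutoffHz))
  stream
}

#' Standard two-stage preprocessing
#'
#' Low-pass each scan, then high-pass each potential step across time, in
#' that order.
#'
#' @param stream a [ScanStream-class].
#' @param lowpassOrder,lowpassCutoffHz per-scan low-pass settings.
#' @param highpassOrder,highpassCutoffHz across-time high-pass settings.
#' @return the preprocessed [ScanStream-class].
#' @export
preprocessStream <- function(stream, lowpassOrder = 4L,
                             lowpassCutoffHz = 2000,
                             highpassOrder = 2L, highpassCutoffHz = 0.01) {
  stream <- lowpassScanFilter(stream, lowpassOrder, lowpassCutoffHz)
  highpassDriftFilter(stream, highpassOrder, highpassCutoffHz)
}
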
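#' Build a triangular FSCV ramp waveform
#'
#' Constructs the applied potential waveform: a symmetric triangular sweep
#' from `vHold` to `vPeak` and back at `scanRate`, repeated at
#' `repetitionRate`. The defaults reproduce the standard dopamine waveform:
#' -0.4 to +1.3 V at 400 V/s, which lasts 8.5 ms, leaving a 91.5 ms hold at
#' -0.4 V when repeated at 10 Hz.
#'
#' @param vHold holding potential, volts.
#' @param vPeak apex potential, volts; must exceed `vHold`.
#' @param scanRate sweep rate, volts per second.
#' @param samplesPerScan digitized points per sweep (1,000 by default).
#' @param repetitionRate sweep repetition rate, hertz (10 for recording,
#'   60 for cycling sessions).
#' @return a [RampWaveform-class].
#' @examples
#' wf <- buildRamp()
#' rampDuration(wf) # 0.0085 s
#' holdDuration(wf) # 0.0915 s
#' @export
buildRamp <- function(vHold = -0.4, vPeak = 1.3, scanRate = 400,
                      samplesPerScan = 1000L, repetitionRate = 10) {
  new("RampWaveform",
      vHold = as.numeric(vHold), vPeak = as.numeric(vPeak),
      scanRate = as.numeric(scanRate),
      samplesPerScan = as.integer(samplesPerScan),
      repetitionRate = as.numeric(repetitionRate))
}

#' Construct a stimulation event
#'
#' @param onsetTime seconds from recording start (default 5 s).
#' @param frequency pulse frequency, hertz.
#' @param pulseCount number of pulses in the train.
#' @param amplitude stimulation current, microamps.
#' @return a [StimEvent-class].
#' @examples
#' stimEvent(frequency = 60, pulseCount = 30L)
#' @export
stimEvent <- function(onsetTime = 5, frequency = 60, pulseCount = 30L,
                      amplitude = 150) {
  new("StimEvent", onsetTime = as.numeric(onsetTime),
      frequency = as.numeric(frequency),
      pulseCount = as.integer(pulseCount),
      amplitude = as.numeric(amplitude))
}

#' Construct a scan stream
#'
#' Wraps a scans-by-samples current matrix with acquisition metadata. Scan
#' times default to `scan index / repetitionRate`.
#'
#' @param scansMatrix numeric matrix, one row per scan, nanoamps.
#' @param channelId 0-based channel index.
#' @param waveform a [RampWaveform-class].
#' @param gain transimpedance gain, nanoamps per volt.
#' @param segmentLength on-disk segment length, seconds.
#' @param scanTimes optional scan onset times; computed when `NULL`.
#' @param meta list of provenance fields.
#' @return a [ScanStream-class].
#' @export
scanStream <- function(scansMatrix, channelId = 0L, waveform = buildRamp(),
                       gain = 200, segmentLength = 30, scanTimes = NULL,
                       meta = list()) {
  scansMatrix <- as.matrix(scansMatrix)
  if (is.null(scanTimes))
    scanTimes <- (seq_len(nrow(scansMatrix)) - 1L) / waveform@repetitionRate
  new("ScanStream", channelId = as.integer(channelId), scans = scansMatrix,
      scanTimes = as.numeric(scanTimes), waveform = waveform,
      gain = as.numeric(gain), segmentLength = as.numeric(segmentLength),
      meta = meta)
}

#' Convert amplifier differential voltage to current
#'
#' The headstage reports current as a differential voltage through a
#' transimpedance gain; `current = volts * gain`.
#'
#' @param differentialVolts measured differential voltage, volts.
#' @param gain nanoamps per volt (200 at the default feedback resistor).
#' @return current in nanoamps.
#' @examples
#' voltsToCurrent(1, 200) # 200 nA
#' @export
voltsToCurrent <- function(differentialVolts, gain = 200) {
  stopifnot(length(gain) == 1L, gain > 0)
  differentialVolts * gain
}

#' Transimpedance gain implied by a feedback resistor
#'
#' `gain = 1/R`, expressed in nanoamps per volt. A 4.99 MOhm resistor gives
#' 200.4 nA/V, i.e. the nominal 200 nA/V gain.
#'
#' @param resistanceOhm feedback resistance, ohms.
#' @return gain in nanoamps per volt.
#' @examples
#' gainFromResistor(4.99e6) # 200.4 nA/V
#' @export
gainFromResistor <- function(resistanceOhm) {
  stopifnot(resistanceOhm > 0)
  1e9 / resistanceOhm
}
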
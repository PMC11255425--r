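wfDefault <- buildRamp()

sineScan <- function(freqHz, wf = wfDefault) {
  t <- (seq_len(wf@samplesPerScan) - 1) / withinScanRate(wf)
  sin(2 * pi * freqHz * t)
}

# amplitude of the freqHz component over the steady-state tail of a scan
sineAmplitude <- function(x, freqHz, wf = wfDefault) {
  t <- (seq_len(wf@samplesPerScan) - 1) / withinScanRate(wf)
  idx <- seq(round(length(x) / 2), length(x))
  X <- cbind(sin(2 * pi * freqHz * t[idx]), cos(2 * pi * freqHz * t[idx]))
  sqrt(sum(qr.solve(X, x[idx])^2))
}

test_that("per-scan low-pass passes DC and realizes the Butterworth response", {
  s <- scanStream(matrix(7.5, 10, 1000), waveform = wfDefault)
  expect_equal(scans(lowpassScanFilter(s)), matrix(7.5, 10, 1000),
               tolerance = 1e-9)

  x <- sineScan(2000)
  y <- scans(lowpassScanFilter(
    scanStream(matrix(x, 1, byrow = TRUE), waveform = wfDefault)))[1, ]
  ratio <- sineAmplitude(y, 2000) / sineAmplitude(x, 2000)
  expect_equal(ratio, 1 / sqrt(2), tolerance = 0.01)

  x10 <- sineScan(20000)
  y10 <- scans(lowpassScanFilter(
    scanStream(matrix(x10, 1, byrow = TRUE), waveform = wfDefault)))[1, ]
  atten <- sineAmplitude(y10, 20000) / sineAmplitude(x10, 20000)
  expect_lt(20 * log10(atten), -70)  # 4th order: -80 dB/decade
})

test_that("low-pass cutoff must stay below the within-scan Nyquist", {
  s <- scanStream(matrix(0, 5, 1000), waveform = wfDefault)
  expect_error(lowpassScanFilter(s, cutoffHz = withinScanRate(wfDefault)),
               "Nyquist")
})

test_that("drift filter removes constants exactly and needs enough scans", {
  s <- scanStream(matrix(3, 50, 100), waveform = buildRamp(samplesPerScan = 100L))
  out <- scans(highpassDriftFilter(s))
  expect_lt(max(abs(out)), 1e-8)

  tiny <- scanStream(matrix(0, 5, 100),
                     waveform = buildRamp(samplesPerScan = 100L))
  expect_error(highpassDriftFilter(tiny), "scans")
})

test_that("drift filter is zero-phase: transient peaks at lag 0", {
  wf <- buildRamp(samplesPerScan = 20L)
  n <- 300
  x <- numeric(n); x[150] <- 1
  s <- scanStream(matrix(x, n, 20), waveform = wf)
  y <- scans(highpassDriftFilter(s))[, 1]
  cc <- stats::ccf(y, x, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("drift filter suppresses slow drift but keeps fast transients", {
  wf <- buildRamp(samplesPerScan = 10L)
  t <- (0:2399) / 10  # 4 min at 10 Hz
  drift <- (1 / 60) * t               # 1 nA per minute
  boxcar <- as.numeric(t >= 120 & t < 122)  # 2 s transient
  mk <- function(v) scanStream(matrix(v, length(v), 10), waveform = wf)
  outDrift <- scans(highpassDriftFilter(mk(drift)))[, 1]
  outBox <- scans(highpassDriftFilter(mk(boxcar)))[, 1]
  expect_lt(diff(range(outDrift)), 0.05 * diff(range(drift)))
  expect_gt(max(outBox), 0.9)
})

test_that("both filter stages are linear", {
  wf <- buildRamp(samplesPerScan = 50L)
  set.seed(4)
  x <- matrix(rnorm(40 * 50), 40, 50)
  y <- matrix(rnorm(40 * 50), 40, 50)
  a <- 2.5; b <- -1.25
  for (f in list(lowpassScanFilter, highpassDriftFilter)) {
    fx <- scans(f(scanStream(x, waveform = wf)))
    fy <- scans(f(scanStream(y, waveform = wf)))
    fmix <- scans(f(scanStream(a * x + b * y, waveform = wf)))
    expect_equal(fmix, a * fx + b * fy, tolerance = 1e-9)
  }
})

test_that("repeated drift filtering stays finite and keeps DC at zero", {
  wf <- buildRamp(samplesPerScan = 10L)
  # pure DC in, exactly nothing out, however often it is applied
  const <- scanStream(matrix(50, 40, 10), waveform = wf)
  twiceConst <- highpassDriftFilter(highpassDriftFilter(const))
  expect_lt(max(abs(scans(twiceConst))), 1e-8)
  # bounded noisy input stays bounded and centered
  set.seed(5)
  s <- scanStream(matrix(rnorm(400, mean = 50), 40, 10), waveform = wf)
  twice <- highpassDriftFilter(highpassDriftFilter(s))
  expect_true(all(is.finite(scans(twice))))
  expect_lt(max(abs(scans(twice))), 10)
})
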
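test_that("ramp arithmetic reproduces the acquisition constants", {
  wf <- buildRamp()
  expect_equal(rampDuration(wf), 0.0085)
  expect_equal(holdDuration(wf), 0.0915)
  expect_equal(rampDuration(wf) + holdDuration(wf),
               1 / wf@repetitionRate)

  wf2 <- buildRamp(0, 1, 1000, 100L, 100)
  expect_equal(rampDuration(wf2), 0.002)
  expect_equal(holdDuration(wf2), 0.008)

  # repetition period shorter than the ramp is an invalid waveform
  expect_error(buildRamp(-0.4, 1.3, 400, 1000L, 200), "shorter")
})

test_that("the sampled voltage sequence is a symmetric triangle", {
  wf <- buildRamp()
  v <- rampVoltages(wf)
  expect_equal(v[1], -0.4)
  expect_equal(max(v), 1.3)
  expect_equal(which.max(v), wf@samplesPerScan / 2 + 1L)  # half-scan apex
  # symmetric about the apex within one sample interval of slope
  slopePerSample <- (wf@vPeak - wf@vHold) / (wf@samplesPerScan / 2)
  expect_lt(abs(v[length(v)] - (-0.4)), slopePerSample + 1e-12)
  expect_lt(max(abs(v - rev(v))), slopePerSample + 1e-12)
})

test_that("gain conversions match the amplifier design", {
  expect_equal(voltsToCurrent(1, 200), 200)
  expect_equal(voltsToCurrent(0, 200), 0)
  expect_equal(gainFromResistor(4.99e6), 200.4008, tolerance = 1e-6)
  expect_equal(round(gainFromResistor(4.99e6)), 200)
})

test_that("raw dialect segments streams in 30 s increments", {
  wf <- buildRamp()
  d <- withr::local_tempdir()
  s30 <- scanStream(matrix(0, 300, 1000), waveform = wf)
  writeRaw(s30, d)
  segs <- list.files(file.path(d, "ch00"), pattern = "i16$",
                     full.names = TRUE)
  expect_length(segs, 1L)
  expect_equal(file.size(segs), 300000 * 2)  # 300 scans x 1000 x int16

  d2 <- withr::local_tempdir()
  s65 <- scanStream(matrix(0, 650, 1000), waveform = wf)
  writeRaw(s65, d2)
  segs2 <- sort(list.files(file.path(d2, "ch00"), pattern = "i16$",
                           full.names = TRUE))
  expect_length(segs2, 3L)
  expect_equal(file.size(segs2) / 2000, c(300, 300, 50))
})

test_that("write -> read round-trips within one quantization step", {
  wf <- buildRamp(samplesPerScan = 120L)
  step <- defaultCountScale()
  set.seed(11)
  for (rep in 1:3) {
    m <- matrix(rnorm(40 * 120, sd = 100), 40, 120)  # within +-2000 nA range
    d <- withr::local_tempdir()
    writeRaw(list(scanStream(m, 0L, wf), scanStream(2 * m, 5L, wf)), d)
    back <- readRaw(d)
    expect_named(back, c("ch00", "ch05"))
    expect_lt(max(abs(scans(back$ch00) - m)), step)
    expect_lt(max(abs(scans(back$ch05) - 2 * m)), step)
    expect_equal(scanTimes(back$ch00), (0:39) / 10)
  }
})

test_that("all-zero counts read back as all-zero currents", {
  d <- withr::local_tempdir()
  wf <- buildRamp(samplesPerScan = 50L)
  writeRaw(scanStream(matrix(0, 20, 50), waveform = wf), d)
  expect_true(all(scans(readRaw(d)$ch00) == 0))
})

test_that("corrupt segments and missing sidecars are rejected", {
  d <- withr::local_tempdir()
  wf <- buildRamp(samplesPerScan = 50L)
  writeRaw(scanStream(matrix(1, 20, 50), waveform = wf), d)
  # truncate a segment to a non-whole number of scans
  f <- list.files(file.path(d, "ch00"), full.names = TRUE)[1]
  writeBin(readBin(f, "raw", n = file.size(f) - 10), f)
  expect_error(readRaw(d), "corrupt")

  d2 <- withr::local_tempdir()
  expect_error(readRaw(d2), "sidecar")
})

test_that("scan stream validity enforces shape and timing", {
  wf <- buildRamp(samplesPerScan = 10L)
  expect_error(scanStream(matrix(0, 5, 9), waveform = wf), "samples")
  expect_error(scanStream(matrix(0, 5, 10), waveform = wf,
                          scanTimes = c(0, 1, 2, 3, 4)), "spacing")
  expect_s4_class(scanStream(matrix(0, 5, 10), waveform = wf),
                  "ScanStream")
})
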
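test_that("kinetics simulation follows first-order release/reuptake", {
  # no pulses -> identically zero
  zero <- simulateKinetics(stimEvent(pulseCount = 1L), releasePerPulse = 0)
  expect_true(all(zero$conc_nM == 0))

  # a single pulse decays as exp(-t/tau) and tau is recoverable
  one <- simulateKinetics(stimEvent(onsetTime = 5, pulseCount = 1L),
                          releasePerPulse = 300, tau = 2)
  post <- one$time >= 5
  expect_equal(one$conc_nM[post],
               300 * exp(-(one$time[post] - 5) / 2), tolerance = 1e-12)
  tr <- applyCalibration(uncalibrate(one$conc_nM, 10), 10, one$time)
  f <- fitTau(tr, 5, 0, 300)
  expect_equal(f$tau, 2, tolerance = 1e-6)

  # more pulses at equal release never lower the peak
  p30 <- simulateKinetics(stimEvent(frequency = 60, pulseCount = 30L))
  p60 <- simulateKinetics(stimEvent(frequency = 60, pulseCount = 60L))
  expect_gte(max(p60$conc_nM), max(p30$conc_nM))

  # monotone in release per pulse
  peaks <- sapply(c(5, 10, 20, 40), function(rp)
    max(simulateKinetics(stimEvent(), releasePerPulse = rp)$conc_nM))
  expect_true(all(diff(peaks) > 0))
})

test_that("scan synthesis is linear in dopamine", {
  wf <- buildRamp()
  tmpl <- voltammogramTemplates(wf)
  bg <- 400 * tmpl$background
  s0 <- synthesizeScan(0, 0, wf, tmpl, 10, bg)
  expect_equal(s0, bg)
  s1 <- synthesizeScan(500, 0, wf, tmpl, 10, bg)
  s2 <- synthesizeScan(1000, 0, wf, tmpl, 10, bg)
  expect_equal(s2 - bg, 2 * (s1 - bg), tolerance = 1e-12)
  shortTmpl <- voltammogramTemplates(buildRamp(samplesPerScan = 100L))
  expect_error(synthesizeScan(100, 0, wf, shortTmpl), "length")
})

test_that("the generator is seed-deterministic down to the raw bytes", {
  cfg <- simConfig(nChannels = 2L, duration = 10)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generateRecording(cfg, seed = 42, dir = d1, returnStreams = FALSE)
  generateRecording(cfg, seed = 42, dir = d2, returnStreams = FALSE)
  f1 <- list.files(d1, recursive = TRUE, pattern = "i16$",
                   full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, pattern = "i16$",
                   full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1))
    expect_identical(readBin(f1[i], "raw", file.size(f1[i])),
                     readBin(f2[i], "raw", file.size(f2[i])))
  # a different seed changes the bytes
  d3 <- withr::local_tempdir()
  generateRecording(cfg, seed = 43, dir = d3, returnStreams = FALSE)
  f3 <- list.files(d3, recursive = TRUE, pattern = "i16$",
                   full.names = TRUE)
  expect_false(identical(readBin(f1[1], "raw", file.size(f1[1])),
                         readBin(f3[1], "raw", file.size(f3[1]))))
})

test_that("ground truth serializes and reads back", {
  d <- withr::local_tempdir()
  r <- generateRecording(simConfig(nChannels = 2L, duration = 10),
                         seed = 5, dir = d)
  tr <- readGroundTruth(d)
  expect_equal(tr@esDa, r$truth@esDa)
  expect_equal(tr@sensitivity, r$truth@sensitivity)
  expect_equal(tr@concentration, r$truth@concentration)
  expect_equal(tr@tau, r$truth@tau)
})

test_that("cross-channel sensitivity dispersion hits the target CV", {
  cfg <- simConfig(nChannels = 16L, duration = 8,
                   waveform = buildRamp(samplesPerScan = 100L),
                   stim = stimEvent(onsetTime = 1),
                   noiseSd = 0, driftStep = 0)
  cvs <- sapply(1:50, function(i) {
    r <- generateRecording(cfg, seed = 100 + i)
    sd(r$truth@esDa) / mean(r$truth@esDa)
  })
  expect_lt(abs(mean(cvs) - 0.27), 0.05)
})

test_that("dropout channels carry no stimulated signal", {
  r <- generateRecording(simConfig(nChannels = 4L, duration = 10,
                                   dropout = 2L, noiseSd = 0,
                                   driftStep = 0, chargingAmp = 0),
                         seed = 3)
  expect_equal(r$truth@esDa[3], 0)
  expect_gt(r$truth@esDa[1], 0)
  # the dropout stream has no transient at the oxidation potential
  dc <- detectedCurrent(r$streams[[3]])
  expect_lt(diff(range(dc)), 1e-9)
})
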
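wf <- buildRamp()
tmpl <- voltammogramTemplates(wf)
trainDefault <- defaultTrainingSet(wf, tmpl)
modelDefault <- fitPCR(trainDefault)

test_that("the canonical training set is 5 DA + 3 acidic + 2 basic", {
  tab <- table(trainDefault@analyte)
  expect_equal(as.integer(tab[c("DA", "acidic_pH", "basic_pH")]),
               c(5L, 3L, 2L))
  expect_equal(ncol(trainDefault@spectra), wf@samplesPerScan)
})

test_that("rank-1 training (multiples of one DA template) retains one component", {
  base <- tmpl$da * 10
  ts <- trainingSet(rbind(base, 2 * base, 4 * base),
                    analyte = rep("DA", 3), magnitude = c(1, 2, 4))
  m <- fitPCR(ts)
  expect_equal(m@k, 1L)
  pred <- predictDA(m, ts@spectra)
  expect_equal(pred$da_nA, c(1, 2, 4) * m@sensitivity, tolerance = 1e-10)
})

test_that("orthogonal DA and pH templates are separated exactly", {
  n <- 100L
  t1 <- c(rep(1, 50), rep(0, 50))   # DA direction
  t2 <- c(rep(0, 50), rep(1, 50))   # pH direction, orthogonal
  ts <- trainingSet(rbind(1 * t1, 2 * t1, -0.1 * t2, -0.2 * t2),
                    analyte = c("DA", "DA", "acidic_pH", "acidic_pH"),
                    magnitude = c(1, 2, -0.1, -0.2))
  m <- fitPCR(ts)
  expect_equal(m@k, 2L)
  mix <- matrix(1.5 * t1 - 0.15 * t2, 1)
  p <- predictDA(m, mix)
  expect_equal(p$da_nA, 1.5 * m@sensitivity, tolerance = 1e-10)
  expect_equal(p$ph, -0.15, tolerance = 1e-10)
})

test_that("prediction equals least squares onto the training spectra", {
  X <- trainDefault@spectra
  daUM <- ifelse(trainDefault@analyte == "DA", trainDefault@magnitude, 0)
  set.seed(8)
  for (i in 1:20) {
    a <- runif(nrow(X), 0, 2)
    x <- drop(a %*% X)
    oracle <- sum(lsOntoSpectra(X, x) * daUM) * modelDefault@sensitivity
    pcr <- predictDA(modelDefault, matrix(x, 1))$da_nA
    expect_equal(pcr, oracle, tolerance = 1e-8)
  }
})

test_that("zero scans, scaled references and training labels behave linearly", {
  p0 <- predictDA(modelDefault, matrix(0, 1, wf@samplesPerScan))
  expect_equal(p0$da_nA, 0)
  expect_lt(p0$q, 1e-20)

  # twice the 1 uM DA reference reads as 2 uM-equivalents of current
  ref <- trainDefault@spectra[trainDefault@magnitude == 1 &
                                trainDefault@analyte == "DA", ]
  p2 <- predictDA(modelDefault, matrix(2 * ref, 1))
  expect_equal(p2$da_nA, 2 * modelDefault@sensitivity, tolerance = 1e-8)

  # training labels are reproduced on the training spectra
  fitted <- predictDA(modelDefault, trainDefault@spectra)$da_nA
  daUM <- ifelse(trainDefault@analyte == "DA", trainDefault@magnitude, 0)
  expect_equal(fitted, daUM * modelDefault@sensitivity, tolerance = 1e-8)

  # linearity of the prediction
  x1 <- trainDefault@spectra[1, ]; x2 <- trainDefault@spectra[7, ]
  pMix <- predictDA(modelDefault, matrix(3 * x1 - 2 * x2, 1))$da_nA
  pParts <- 3 * predictDA(modelDefault, matrix(x1, 1))$da_nA -
    2 * predictDA(modelDefault, matrix(x2, 1))$da_nA
  expect_equal(pMix, pParts, tolerance = 1e-10)
})

test_that("DA estimates ignore pH components inside the training space", {
  ref <- trainDefault@spectra[trainDefault@magnitude == 1 &
                                trainDefault@analyte == "DA", ]
  acid <- trainDefault@spectra[trainDefault@analyte == "acidic_pH", ][1, ]
  basic <- trainDefault@spectra[trainDefault@analyte == "basic_pH", ][1, ]
  base <- predictDA(modelDefault, matrix(ref, 1))$da_nA
  for (alpha in c(-3, 0.5, 10)) {
    p <- predictDA(modelDefault,
                   matrix(ref + alpha * acid + 2 * alpha * basic, 1))$da_nA
    expect_equal(p, base, tolerance = 1e-8)
  }
})

test_that("components orthogonal to the training space trip the Q flag", {
  # a feature direction the references never contain
  odd <- numeric(wf@samplesPerScan)
  odd[seq(3, 900, by = 7)] <- 5
  p <- predictDA(modelDefault, matrix(odd, 1))
  expect_gt(p$q, modelDefault@qThreshold)
  expect_true(p$flagged)
})

test_that("degenerate inputs are rejected", {
  zeroTs <- trainingSet(matrix(0, 3, 10), analyte = rep("DA", 3),
                        magnitude = 1:3)
  expect_error(fitPCR(zeroTs), "degenerate")
  expect_error(predictDA(modelDefault, matrix(0, 1, 99)), "length")
  twoRow <- trainingSet(rbind(tmpl$da, 2 * tmpl$da),
                        analyte = c("DA", "DA"), magnitude = c(1, 2))
  expect_error(fitPCR(twoRow), "at least 3")
})

test_that("a synthesized scan round-trips through the chemometric model", {
  scan <- synthesizeScan(750, 0, wf, tmpl, sensitivity = 10)
  s <- scanStream(matrix(scan, 1, byrow = TRUE), waveform = wf)
  filtered <- scans(lowpassScanFilter(s))
  est <- predictDA(modelDefault, filtered)$da_nA / modelDefault@sensitivity
  expect_equal(est, 0.75, tolerance = 0.01)  # 750 nM = 0.75 uM
})
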
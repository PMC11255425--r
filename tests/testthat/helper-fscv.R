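# Shared fixtures are built in code; nothing is read from disk.

# Minimum-norm least-squares coefficients of x onto the rows of X
# (independent oracle for the chemometrics tests).
lsOntoSpectra <- function(X, x) {
  s <- svd(t(X))
  tol <- max(dim(X)) * max(s$d) * 1e-12
  k <- s$d > tol
  drop(s$v[, k, drop = FALSE] %*%
         ((t(s$u[, k, drop = FALSE]) %*% x) / s$d[k]))
}

# A small clean (noise/drift-free, uniform-sensitivity) recording config.
cleanConfig <- function(nChannels = 2L, ...) {
  simConfig(nChannels = nChannels, noiseSd = 0, driftStep = 0,
            chargingAmp = 0, sensitivityCV = 0, ...)
}

# Flat-baseline concentration trace helper.
concTrace <- function(conc, dt = 0.1, channel = 0L) {
  applyCalibration(uncalibrate(conc, 10), 10,
                   time = (seq_along(conc) - 1) * dt, channelId = channel)
}
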
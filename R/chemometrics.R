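# Principal component regression chemometrics. Reference voltammograms are
# background-subtracted, so zero analyte corresponds to the zero spectrum and
# the decomposition is taken through the origin: the SVD of the (uncentered)
# training matrix supplies the retained directions, and a through-origin
# least-squares map takes component scores to analyte magnitudes. The DA
# output is expressed as DA-equivalent current (nA) -- label concentration
# times the training electrode's sensitivity -- so that the conversion to
# molar concentration is performed by the electrode calibration factor
# downstream, mirroring the measurement chain.

#' Construct a chemometric training set
#'
#' @param spectra matrix of background-subtracted reference voltammograms,
#'   one row per reference, nanoamps.
#' @param analyte `"DA"`, `"acidic_pH"` or `"basic_pH"` per row.
#' @param magnitude known magnitude per row: micromolar for DA rows, signed
#'   pH shift for pH rows.
#' @return a [TrainingSet-class].
#' @seealso [defaultTrainingSet()] for the canonical synthetic 5 DA + 3
#'   acidic + 2 basic composition.
#' @export
trainingSet <- function(spectra, analyte, magnitude) {
  new("TrainingSet", spectra = as.matrix(spectra),
      analyte = as.character(analyte), magnitude = as.numeric(magnitude))
}

#' Fit a principal component regression model
#'
#' Decomposes the training spectra by singular value decomposition (through
#' the origin; references are background-subtracted), retains the smallest
#' number of components whose cumulative explained variance reaches
#' `varianceKeep` (capped at rows - 1), and fits a least-squares map from
#' retained scores to analyte magnitudes. The DA regression target is the
#' label concentration times the training electrode sensitivity (the
#' through-origin slope of DA-row oxidation-peak current versus label
#' concentration), so predictions come out in DA-equivalent nanoamps. The
#' residual (Q) flagging threshold is set at the `qQuantile` quantile of the
#' training-spectrum residuals.
#'
#' @param training a [TrainingSet-class] (rows >= 3, at least one DA row).
#' @param varianceKeep cumulative explained-variance target in (0, 1].
#' @param qQuantile quantile of training residuals used as `qThreshold`.
#' @param center subtract the training mean before decomposition. Off by
#'   default: centering breaks the through-origin correspondence between
#'   spectra and magnitudes that background subtraction provides.
#' @return a [PCRModel-class].
#' @export
fitPCR <- function(training, varianceKeep = 0.995, qQuantile = 0.95,
                   center = FALSE) {
  stopifnot(is(training, "TrainingSet"))
  validObject(training)
  X <- training@spectra
  if (nrow(X) < 3L) stop("need at least 3 training spectra")
  mu <- colMeans(X)
  Xd <- if (center) sweep(X, 2L, mu) else X
  sv <- svd(Xd)
  tot <- sum(sv$d^2)
  if (tot < 1e-20) stop("degenerate training matrix: zero variance")
  cumvar <- cumsum(sv$d^2) / tot
  kMax <- max(1L, min(nrow(X) - 1L, sum(sv$d > sv$d[1L] * 1e-10)))
  k <- min(which(cumvar >= varianceKeep), kMax)
  V <- sv$v[, seq_len(k), drop = FALSE]
  scores <- Xd %*% V

  isDA <- training@analyte == "DA"
  daUM <- ifelse(isDA, training@magnitude, 0)
  phShift <- ifelse(isDA, 0, training@magnitude)
  peaks <- apply(X[isDA, , drop = FALSE], 1L, max)
  sens <- sum(peaks * training@magnitude[isDA]) /
    sum(training@magnitude[isDA]^2)
  if (!is.finite(sens) || sens <= 0)
    stop("could not estimate a positive training sensitivity")

  Y <- cbind(da_nA = daUM * sens, ph = phShift)
  B <- qr.solve(scores, Y)
  resid <- Xd - scores %*% t(V)
  qTrain <- rowSums(resid^2)
  new("PCRModel", meanSpectrum = mu, components = V, k = as.integer(k),
      regressionMap = B, sensitivity = sens,
      qThreshold = as.numeric(stats::quantile(qTrain, qQuantile)),
      varianceExplained = cumvar[k])
}

#' Predict dopamine from voltammogram scans
#'
#' Projects each scan onto the retained principal directions, applies the
#' regression map, and computes the residual statistic Q (squared norm of the
#' part of the scan outside the retained component space). Scans with Q above
#' the threshold are flagged but their values are retained.
#'
#' @param model a [PCRModel-class].
#' @param newdata a preprocessed [ScanStream-class] or a scans-by-samples
#'   matrix whose row length matches the model spectra.
#' @param qThreshold optional override of the model's Q threshold (e.g. one
#'   estimated from baseline scans of the same recording).
#' @return data.frame with one row per scan: `da_nA` (DA-equivalent
#'   current), `ph` (pH-shift estimate), `q`, `flagged`.
#' @export
predictDA <- function(model, newdata, qThreshold = NULL) {
  stopifnot(is(model, "PCRModel"))
  S <- if (is(newdata, "ScanStream")) scans(newdata) else as.matrix(newdata)
  p <- nrow(model@components)
  if (ncol(S) != p)
    stop(sprintf("scan length %d does not match model spectra length %d",
                 ncol(S), p))
  scores <- S %*% model@components
  pred <- scores %*% model@regressionMap
  resid <- S - scores %*% t(model@components)
  q <- rowSums(resid^2)
  thr <- if (is.null(qThreshold)) model@qThreshold else qThreshold
  data.frame(da_nA = pred[, "da_nA"], ph = pred[, "ph"], q = q,
             flagged = q > thr)
}

#' Estimate a Q threshold from baseline scans
#'
#' Reference spectra are typically far cleaner than in-vivo scans, so the
#' training-derived Q threshold can flag every measurement. This helper sets
#' the threshold from the residuals of pre-stimulation baseline scans:
#' `median(Q) + nMad * mad(Q)`.
#'
#' @param q per-scan residuals of the baseline portion of a recording.
#' @param nMad robust multiplier.
#' @return a scalar threshold.
#' @export
baselineQThreshold <- function(q, nMad = 5) {
  stats::median(q) + nMad * stats::mad(q)
}
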
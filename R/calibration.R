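# Flow-cell calibration: boluses of known dopamine concentration (0.5, 1, 2,
# 4 uM, three boluses each) are measured three times per bolus -- at the
# onset peak, just before the washout falloff, and midway between -- and the
# per-concentration means are fitted by a through-origin least-squares line
# whose slope is the electrode sensitivity (nA/uM).

#' Measure flow-cell bolus responses
#'
#' For each bolus window, samples the current at three landmarks: the onset
#' peak (maximum in the first third of the window), the pre-falloff point
#' (last sample at or above 90% of the plateau level) and the temporal
#' midpoint between the two, and averages them. Windows without a detectable
#' plateau (pre-falloff at or before the onset peak) are flagged and excluded
#' with a warning.
#'
#' @param current current trace, nanoamps.
#' @param time sample times, seconds.
#' @param bolusWindows data.frame with columns `concentration_uM`, `start`,
#'   `end` (seconds), one row per bolus.
#' @return data.frame with one row per bolus: `concentration_uM`, `bolus`,
#'   `mean_current_nA`, `valid`.
#' @seealso [fitCalibrationCurve()]
#' @export
measureBolusResponse <- function(current, time, bolusWindows) {
  stopifnot(length(current) == length(time),
            all(c("concentration_uM", "start", "end") %in%
                  names(bolusWindows)))
  out <- lapply(seq_len(nrow(bolusWindows)), function(i) {
    w <- bolusWindows[i, ]
    idx <- which(time >= w$start & time <= w$end)
    if (length(idx) < 3L)
      return(data.frame(concentration_uM = w$concentration_uM, bolus = i,
                        mean_current_nA = NA_real_, valid = FALSE))
    cur <- current[idx]
    nFirst <- max(1L, floor(length(idx) / 3))
    iOnset <- which.max(cur[seq_len(nFirst)])
    plateau <- stats::median(cur[cur >= 0.5 * max(cur)])
    above <- which(cur >= 0.9 * plateau)
    iFall <- if (length(above)) max(above) else iOnset
    valid <- iFall > iOnset
    iMid <- floor((iOnset + iFall) / 2)
    m <- mean(cur[c(iOnset, iMid, iFall)])
    data.frame(concentration_uM = w$concentration_uM, bolus = i,
               mean_current_nA = m, valid = valid)
  })
  res <- do.call(rbind, out)
  if (any(!res$valid))
    warning(sum(!res$valid),
            " bolus window(s) without a detectable plateau were excluded")
  res
}

#' Fit a calibration curve
#'
#' Averages bolus responses per concentration and fits current versus
#' concentration by least squares. The default is a through-origin fit (zero
#' dopamine implies zero faradaic current), whose slope is the closed-form
#' `sum(conc * current) / sum(conc^2)`; an intercept can be requested.
#'
#' @param concentrations micromolar, one per mean current (repeats allowed;
#'   they are averaged per unique concentration first).
#' @param meanCurrents nanoamps.
#' @param intercept fit an intercept term instead of forcing the origin.
#' @param allowSingle permit a single-concentration calibration (factor =
#'   current/concentration); otherwise at least two concentrations are
#'   required.
#' @return a [CalibrationCurve-class].
#' @examples
#' fitCalibrationCurve(c(0.5, 1, 2, 4), c(5, 10, 20, 40)) # factor 10 nA/uM
#' @export
fitCalibrationCurve <- function(concentrations, meanCurrents,
                                intercept = FALSE, allowSingle = FALSE) {
  keep <- is.finite(meanCurrents) & is.finite(concentrations)
  concentrations <- concentrations[keep]
  meanCurrents <- meanCurrents[keep]
  conc <- sort(unique(concentrations))
  cur <- vapply(conc, function(cc)
    mean(meanCurrents[concentrations == cc]), numeric(1))
  if (length(conc) < 2L) {
    if (!allowSingle || length(conc) == 0L)
      stop("need mean currents at >=2 concentrations (or allowSingle=TRUE)")
    f <- cur / conc
    if (f <= 0) stop("calibration failure: nonpositive sensitivity")
    return(new("CalibrationCurve", concentrations = conc, meanCurrents = cur,
               factor = f, fitResidual = 0))
  }
  if (intercept) {
    fit <- stats::lm(cur ~ conc)
    f <- unname(stats::coef(fit)[2L])
    resid <- sqrt(mean(stats::resid(fit)^2))
  } else {
    f <- sum(conc * cur) / sum(conc^2)
    resid <- sqrt(mean((cur - f * conc)^2))
  }
  if (!is.finite(f) || f <= 0)
    stop("calibration failure: nonpositive sensitivity slope")
  new("CalibrationCurve", concentrations = conc, meanCurrents = cur,
      factor = f, fitResidual = resid)
}

#' Read a flow-cell calibration table
#'
#' Reads a CSV with columns `concentration_uM`, `bolus_id`,
#' `mean_current_nA` (one row per bolus measurement) and fits the
#' calibration curve.
#'
#' @param path CSV path.
#' @param ... passed to [fitCalibrationCurve()].
#' @return a [CalibrationCurve-class].
#' @export
readCalibrationTable <- function(path, ...) {
  tab <- utils::read.csv(path)
  stopifnot(all(c("concentration_uM", "mean_current_nA") %in% names(tab)))
  fitCalibrationCurve(tab$concentration_uM, tab$mean_current_nA, ...)
}

#' Convert a DA current trace to concentration
#'
#' `concentration(t) = current(t) / factor`, reported in nanomolar. `factor`
#' may be a [CalibrationCurve-class] or a bare sensitivity in nA/uM.
#'
#' @param daCurrent DA-equivalent current per scan, nanoamps (e.g. the
#'   `da_nA` column of [predictDA()]).
#' @param factor calibration factor, nanoamps per micromolar, or a
#'   [CalibrationCurve-class].
#' @param time scan times, seconds.
#' @param channelId 0-based channel index.
#' @param q,flagged optional per-scan chemometric residuals and flags.
#' @return a [ConcentrationTrace-class] in nanomolar.
#' @examples
#' tr <- applyCalibration(rep(10, 8), 10, time = 0:7 / 10)
#' concentration(tr)[1] # 1000 nM
#' @export
applyCalibration <- function(daCurrent, factor, time, channelId = 0L,
                             q = numeric(0), flagged = logical(0)) {
  if (is(factor, "CalibrationCurve")) factor <- factor@factor
  stopifnot(length(factor) == 1L, factor > 0)
  new("ConcentrationTrace", channelId = as.integer(channelId),
      time = as.numeric(time),
      concentration = 1000 * daCurrent / factor,
      q = as.numeric(q), flagged = as.logical(flagged),
      flags = character(0), calibrationFactor = factor)
}

#' Invert a calibration (concentration back to current)
#'
#' @param concentrationNM concentration, nanomolar.
#' @param factor nanoamps per micromolar or a [CalibrationCurve-class].
#' @return DA-equivalent current, nanoamps.
#' @export
uncalibrate <- function(concentrationNM, factor) {
  if (is(factor, "CalibrationCurve")) factor <- factor@factor
  stopifnot(factor > 0)
  concentrationNM * factor / 1000
}
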
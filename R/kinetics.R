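# ES DA and Tau quantification. ES DA is the difference between the
# pre-stimulation baseline [DA] and the peak [DA] reached within 10 s of
# stimulation onset. Tau is the time constant of a single-exponential fit to
# the post-peak decay, from the peak down to the return to 10% of ES DA
# above baseline; larger Tau means slower reuptake.

.traceValues <- function(trace) {
  # Q-flag policy: <=20% flagged -> linear interpolation across flagged
  # scans; more -> drop flagged samples; if fewer than 10 samples would
  # remain, keep everything and flag the result as degenerate.
  conc <- concentration(trace)
  t <- trace@time
  fl <- trace@flagged
  extra <- character(0)
  if (length(fl) == length(conc) && any(fl)) {
    frac <- mean(fl)
    if (frac <= 0.2) {
      if (any(!fl))
        conc[fl] <- stats::approx(t[!fl], conc[!fl], xout = t[fl],
                                  rule = 2)$y
      extra <- "q_interpolated"
    } else if (sum(!fl) >= 10L) {
      t <- t[!fl]; conc <- conc[!fl]
      extra <- "q_excluded"
    } else {
      extra <- "qc_degenerate"
    }
  }
  list(time = t, conc = conc, flags = extra)
}

#' Quantify stimulated dopamine release (ES DA)
#'
#' Baseline is the mean concentration over the `baselineWindow` seconds
#' ending at stimulation onset; the peak is the maximum within
#' `(onset, onset + peakWindow]`; ES DA is their difference. A nonpositive
#' difference is reported but flagged `"no_response"`.
#'
#' @param trace a [ConcentrationTrace-class] covering at least
#'   `[onset - baselineWindow, onset + peakWindow]`.
#' @param stim a [StimEvent-class].
#' @param baselineWindow pre-stimulation window length, seconds.
#' @param peakWindow post-onset search window, seconds (10 s by the ES DA
#'   definition).
#' @return a [KineticsResult-class] with `tau` unset (`NA`); see
#'   [quantifyKinetics()] for the combined estimate.
#' @export
esDaRelease <- function(trace, stim, baselineWindow = 2, peakWindow = 10) {
  stopifnot(is(trace, "ConcentrationTrace"), is(stim, "StimEvent"))
  tv <- .traceValues(trace)
  t <- tv$time; conc <- tv$conc
  onset <- stim@onsetTime
  if (min(t) > onset - baselineWindow + 1e-9 || max(t) < onset + peakWindow - 1e-9)
    stop(sprintf(
      "trace [%.2f, %.2f] s does not cover [%.2f, %.2f] s",
      min(t), max(t), onset - baselineWindow, onset + peakWindow))
  baseIdx <- which(t >= onset - baselineWindow & t <= onset)
  peakIdx <- which(t > onset & t <= onset + peakWindow)
  baseline <- mean(conc[baseIdx])
  iPeak <- peakIdx[which.max(conc[peakIdx])]
  peak <- conc[iPeak]
  es <- peak - baseline
  flags <- tv$flags
  if (es <= 0) flags <- c(flags, "no_response")
  new("KineticsResult", channelId = trace@channelId, esDa = es,
      baseline = baseline, peak = peak, peakTime = t[iPeak],
      tau = NA_real_, tauR2 = NA_real_, flags = flags)
}

#' Fit the clearance time constant Tau
#'
#' Nonlinear least squares of `c(t) = baseline + A * exp(-(t - peakTime) /
#' tau)` over the decay segment from the peak to the first return to
#' `fitEndFraction` of ES DA above baseline (trace end if never reached).
#' Tau is bounded to (0, 60] seconds. A non-decaying segment or a failed fit
#' returns `tau = NA` with flag `"fit_failed"`.
#'
#' @param trace a [ConcentrationTrace-class].
#' @param peakTime time of the ES DA peak, seconds.
#' @param baseline pre-stimulation baseline, nanomolar.
#' @param esDa stimulated release amplitude, nanomolar; must be positive.
#' @param fitEndFraction decay endpoint as a fraction of `esDa` above
#'   baseline.
#' @param tauMax upper bound on tau, seconds.
#' @return list with `tau` (seconds), `r2`, `flags`.
#' @export
fitTau <- function(trace, peakTime, baseline, esDa, fitEndFraction = 0.1,
                   tauMax = 60) {
  stopifnot(is(trace, "ConcentrationTrace"), esDa > 0)
  tv <- .traceValues(trace)
  t <- tv$time; conc <- tv$conc
  seg <- which(t >= peakTime)
  endLevel <- baseline + fitEndFraction * esDa
  below <- seg[conc[seg] <= endLevel]
  if (length(below)) seg <- seg[seg <= below[1L]]
  if (length(seg) < 5L)
    return(list(tau = NA_real_, r2 = NA_real_,
                flags = c(tv$flags, "fit_failed")))
  ts <- t[seg] - peakTime
  y <- conc[seg]
  # crude decay check and log-linear starting value
  if (y[length(y)] >= y[1L])
    return(list(tau = NA_real_, r2 = NA_real_,
                flags = c(tv$flags, "fit_failed")))
  pos <- y - baseline
  ok <- pos > 0.01 * esDa
  tau0 <- if (sum(ok) >= 3L) {
    sl <- stats::coef(stats::lm(log(pos[ok]) ~ ts[ok]))[2L]
    if (is.finite(sl) && sl < 0) min(tauMax, max(1e-3, -1 / sl)) else 1
  } else 1
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ baseline + A * exp(-ts / tau),
      start = list(A = max(esDa, 1e-9), tau = tau0),
      lower = c(A = 0, tau = 1e-4), upper = c(A = Inf, tau = tauMax),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(tau = NA_real_, r2 = NA_real_,
                flags = c(tv$flags, "fit_failed")))
  tau <- unname(stats::coef(fit)["tau"])
  r2 <- 1 - sum(stats::resid(fit)^2) / max(sum((y - mean(y))^2), 1e-300)
  list(tau = tau, r2 = r2, flags = tv$flags)
}

#' Quantify ES DA and Tau for one stimulation event
#'
#' Runs [esDaRelease()] and, when a positive response was found, [fitTau()]
#' on the decay, returning the combined [KineticsResult-class].
#'
#' @inheritParams esDaRelease
#' @inheritParams fitTau
#' @return a [KineticsResult-class].
#' @export
quantifyKinetics <- function(trace, stim, baselineWindow = 2,
                             peakWindow = 10, fitEndFraction = 0.1,
                             tauMax = 60) {
  res <- esDaRelease(trace, stim, baselineWindow, peakWindow)
  if (res@esDa > 0) {
    tf <- fitTau(trace, res@peakTime, res@baseline, res@esDa,
                 fitEndFraction, tauMax)
    res@tau <- tf$tau
    res@tauR2 <- tf$r2
    res@flags <- unique(c(res@flags, tf$flags))
  }
  res
}

#' Flatten kinetics results to a table
#'
#' @param results list of [KineticsResult-class] objects.
#' @return data.frame with one row per channel: `channel`, `es_da_nM`,
#'   `baseline_nM`, `peak_nM`, `peak_time_s`, `tau_s`, `r2`, `flags`.
#' @export
kineticsTable <- function(results) {
  do.call(rbind, lapply(results, function(r) data.frame(
    channel = r@channelId, es_da_nM = r@esDa, baseline_nM = r@baseline,
    peak_nM = r@peak, peak_time_s = r@peakTime, tau_s = r@tau,
    r2 = r@tauR2, flags = paste(r@flags, collapse = ";"))))
}
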
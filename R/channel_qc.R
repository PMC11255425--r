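# Cross-channel QC for the 16-fiber array: a channel whose calculated
# concentration falls outside the mean of all contributing channels +- 2
# sample standard deviations is an outlier and is removed. The rule is a
# single pass by design -- it is never re-iterated on the kept set.

#' Remove outlier channels by the +-n SD rule
#'
#' Computes the mean and sample (n-1) standard deviation over all
#' contributing channels (including each candidate) and removes channels
#' whose value deviates from the mean by more than `nSd` standard
#' deviations. One pass only.
#'
#' @param values named or unnamed numeric vector, one concentration (nM) per
#'   channel; `NA`s are dropped before testing.
#' @param nSd number of standard deviations (2 by default; `Inf` disables
#'   removal).
#' @return list with `kept` (indices into `values`), `outliers` (indices),
#'   `mean`, `sd`, `bounds` (length-2), and `skipped` (TRUE when fewer than
#'   3 channels were available and QC was skipped with a warning).
#' @examples
#' removeOutlierChannels(c(rep(10, 15), 100))$outliers # channel 16
#' @export
removeOutlierChannels <- function(values, nSd = 2) {
  idx <- which(is.finite(values))
  if (length(idx) < 3L) {
    warning("fewer than 3 channels with values; outlier QC skipped")
    return(list(kept = idx, outliers = integer(0), mean = NA_real_,
                sd = NA_real_, bounds = c(NA_real_, NA_real_),
                skipped = TRUE))
  }
  v <- values[idx]
  m <- mean(v)
  s <- stats::sd(v)
  if (is.finite(nSd)) {
    lo <- m - nSd * s
    hi <- m + nSd * s
    out <- idx[v < lo | v > hi]
  } else {
    lo <- -Inf; hi <- Inf
    out <- integer(0)
  }
  list(kept = setdiff(idx, out), outliers = out, mean = m, sd = s,
       bounds = c(lo, hi), skipped = FALSE)
}

#' Per-channel availability across sessions
#'
#' Chronic fibers drop below threshold or become outliers on some days and
#' can come back online later; this tallies per-channel status across
#' sessions.
#'
#' @param sessions a data.frame with columns `session`, `channel`,
#'   `qc_status` (one of `"ok"`, `"below_threshold"`, `"outlier"`,
#'   `"absent"`), or a list of per-session data.frames with `channel` and
#'   `qc_status` (list names become session labels).
#' @return list with `table` (channels x sessions status matrix) and
#'   `summary` (per channel: sessions available, sessions total, yield).
#' @export
channelYieldReport <- function(sessions) {
  if (is.data.frame(sessions)) {
    long <- sessions
  } else {
    stopifnot(length(sessions) >= 1L)
    nm <- names(sessions)
    if (is.null(nm)) nm <- as.character(seq_along(sessions))
    long <- do.call(rbind, lapply(seq_along(sessions), function(i)
      cbind(session = nm[i], sessions[[i]][, c("channel", "qc_status")])))
  }
  stopifnot(all(c("session", "channel", "qc_status") %in% names(long)))
  chans <- sort(unique(long$channel))
  sess <- unique(long$session)
  tab <- matrix("absent", nrow = length(chans), ncol = length(sess),
                dimnames = list(sprintf("ch%02d", chans), sess))
  for (i in seq_len(nrow(long)))
    tab[match(long$channel[i], chans), match(long$session[i], sess)] <-
      long$qc_status[i]
  avail <- rowSums(tab == "ok")
  summary <- data.frame(
    channel = chans,
    sessions_available = as.integer(avail),
    sessions_total = length(sess),
    yield = avail / length(sess)
  )
  list(table = tab, summary = summary)
}
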
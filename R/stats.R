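# Group statistics layer: one-way and factorial ANOVA with Tukey /
# Bonferroni / Sidak post-hocs, Greenhouse-Geisser (GG) sphericity
# correction for repeated measures, REML mixed models across weekly
# sessions (missingness tolerated), and the fiber-variability CV table.
# Significance threshold throughout is p < 0.05.

#' One-way ANOVA with Tukey post-hocs
#'
#' @param values numeric response.
#' @param group grouping factor (>=2 groups, >=2 values each).
#' @return list with `F`, `df` (length 2), `p`, `tukey` (pairwise
#'   data.frame), and the fitted `aov` object.
#' @export
anovaOneway <- function(values, group) {
  group <- factor(group)
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]; group <- droplevels(group[keep])
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("every group needs at least 2 values")
  fit <- stats::aov(values ~ group)
  s <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$group
  list(F = s[1L, "F value"], df = c(s[1L, "Df"], s[2L, "Df"]),
       p = s[1L, "Pr(>F)"],
       tukey = data.frame(comparison = rownames(tk), tk,
                          row.names = NULL, check.names = FALSE),
       fit = fit)
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity correction factor computed from a within-subject covariance
#' matrix: with `S_c` the double-centered covariance of the k repeated
#' levels, `epsilon = tr(S_c)^2 / ((k-1) * tr(S_c^2))`, bounded to
#' `[1/(k-1), 1]`. Compound-symmetric covariance gives exactly 1.
#'
#' @param x either a subjects x levels matrix of responses (residuals after
#'   removing group effects are appropriate) or a k x k covariance matrix.
#' @param isCovariance set `TRUE` when `x` is already a covariance matrix.
#' @return epsilon in `[1/(k-1), 1]`.
#' @export
ggEpsilon <- function(x, isCovariance = FALSE) {
  S <- if (isCovariance) as.matrix(x) else stats::cov(as.matrix(x),
                                                      use = "complete.obs")
  k <- ncol(S)
  if (k < 2L) stop("need at least 2 repeated levels")
  C <- diag(k) - 1 / k
  Sc <- C %*% S %*% C
  eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc * Sc))
  min(1, max(1 / (k - 1), eps))
}

.posthocAdjust <- function(method) {
  switch(method, bonferroni = "bonferroni", sidak = "sidak",
         tukey = "tukey", none = "none",
         stop("unknown post-hoc method: ", method))
}

#' Two-way (factorial or split-plot) ANOVA
#'
#' Between-subjects factorial ANOVA of `response ~ A * B`, or, when `within`
#' names one of the factors and `subject` is given, a split-plot
#' repeated-measures ANOVA with `Error(subject/within)` strata. With
#' `ggCorrection = TRUE` the within-factor and interaction degrees of
#' freedom are multiplied by the Greenhouse-Geisser epsilon estimated from
#' the within-subject covariance (group means removed), and p-values are
#' recomputed. Post-hoc pairwise comparisons of the A x B cell means use the
#' requested multiplicity correction.
#'
#' @param data data.frame in long format.
#' @param response,factorA,factorB column names.
#' @param subject subject/fiber id column (required for the repeated path).
#' @param within `NULL`, or the name of the within-subject factor (must be
#'   `factorB` or `factorA`).
#' @param ggCorrection apply the Greenhouse-Geisser df correction to
#'   within-subject tests.
#' @param posthoc `"bonferroni"`, `"sidak"`, `"tukey"` or `"none"`.
#' @return list with `effects` (data.frame: term, df1, df2, F, p, and when
#'   corrected `epsilon`, `p_gg`), `posthoc` (data.frame or `NULL`),
#'   `epsilon` (or `NA`).
#' @export
anovaTwoway <- function(data, response, factorA, factorB, subject = NULL,
                        within = NULL, ggCorrection = FALSE,
                        posthoc = "bonferroni") {
  df <- data.frame(
    y = data[[response]],
    A = factor(data[[factorA]]),
    B = factor(data[[factorB]]))
  if (!is.null(subject)) df$id <- factor(data[[subject]])
  keep <- is.finite(df$y)
  df <- droplevels(df[keep, ])
  if (is.null(within)) {
    if (any(table(df$A, df$B) == 0L))
      stop("empty cell in the factorial table; use the mixed-model path")
    fit <- stats::aov(y ~ A * B, data = df)
    s <- summary(fit)[[1L]]
    terms <- c("A", "B", "A:B")
    eff <- data.frame(
      term = c(factorA, factorB, paste(factorA, factorB, sep = ":")),
      df1 = s[seq_len(3L), "Df"], df2 = s[4L, "Df"],
      F = s[seq_len(3L), "F value"], p = s[seq_len(3L), "Pr(>F)"])
    eps <- NA_real_
  } else {
    if (is.null(subject)) stop("the repeated path needs a subject column")
    wFac <- if (within == factorB) "B" else if (within == factorA) "A" else
      stop("'within' must name factorA or factorB")
    bFac <- setdiff(c("A", "B"), wFac)
    # cell means per subject x within level (collapse replicates)
    agg <- stats::aggregate(y ~ id + A + B, data = df, FUN = mean)
    form <- stats::as.formula(sprintf("y ~ A * B + Error(id/%s)", wFac))
    fit <- stats::aov(form, data = agg)
    sm <- summary(fit)
    # between stratum: the between factor; within stratum: within + interaction
    betweenTab <- sm[[grep("id$", names(sm))]][[1L]]
    withinTab <- sm[[grep(sprintf("id:%s", wFac), names(sm))]][[1L]]
    rn <- function(tab) trimws(rownames(tab))
    bRow <- match(bFac, rn(betweenTab))
    wRow <- match(wFac, rn(withinTab))
    iRow <- match("A:B", rn(withinTab))
    eff <- data.frame(
      term = c(if (bFac == "A") factorA else factorB, within,
               paste(factorA, factorB, sep = ":")),
      df1 = c(betweenTab[bRow, "Df"], withinTab[c(wRow, iRow), "Df"]),
      df2 = c(betweenTab[rn(betweenTab) == "Residuals", "Df"],
              rep(withinTab[rn(withinTab) == "Residuals", "Df"], 2L)),
      F = c(betweenTab[bRow, "F value"],
            withinTab[c(wRow, iRow), "F value"]),
      p = c(betweenTab[bRow, "Pr(>F)"],
            withinTab[c(wRow, iRow), "Pr(>F)"]))
    # GG epsilon from the within-subject covariance, group means removed
    wide <- stats::reshape(
      agg[, c("id", wFac, "y")], direction = "wide", idvar = "id",
      timevar = wFac)
    mat <- as.matrix(wide[, -1L, drop = FALSE])
    gmeans <- colMeans(mat, na.rm = TRUE)
    eps <- ggEpsilon(sweep(mat, 2L, gmeans))
    if (ggCorrection) {
      eff$epsilon <- c(NA, eps, eps)
      eff$p_gg <- eff$p
      for (r in 2:3)
        eff$p_gg[r] <- stats::pf(eff$F[r], eff$df1[r] * eps,
                                 eff$df2[r] * eps, lower.tail = FALSE)
    }
  }
  ph <- NULL
  if (posthoc != "none") {
    adj <- .posthocAdjust(posthoc)
    em <- emmeans::emmeans(fit, ~ A:B, data = if (is.null(within)) df else agg)
    ph <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                          adjust = adj))
  }
  list(effects = eff, posthoc = ph, epsilon = eps)
}

#' Mixed model across weekly sessions
#'
#' REML linear mixed model for long tables where not every fiber has a value
#' at every time point: `response ~ between * within + (1 | unit)`, fitted
#' with `lmerTest` (Satterthwaite denominator degrees of freedom). Weeks
#' (within levels) with zero observations are dropped with a warning. With
#' `ggCorrection = TRUE`, within-factor and interaction degrees of freedom
#' are scaled by the Greenhouse-Geisser epsilon estimated from the
#' unit-by-level covariance (complete pairs, group means removed). Marginal
#' mean pairwise comparisons between groups within each level use the
#' configured correction.
#'
#' @param data long-format data.frame.
#' @param response response column name.
#' @param between between-units factor column (e.g. sex or group).
#' @param within repeated factor column (e.g. week).
#' @param unit grouping unit column (e.g. fiber).
#' @param ggCorrection apply the Greenhouse-Geisser df correction.
#' @param posthoc `"tukey"`, `"sidak"`, `"bonferroni"` or `"none"`.
#' @return list with `effects` (term, df1, df2, F, p, optionally `epsilon`,
#'   `p_gg`), `posthoc`, `epsilon`, and the fitted `model`.
#' @export
mixedModelWeeks <- function(data, response = "es_da_nM", between = "group",
                            within = "week", unit = "fiber",
                            ggCorrection = TRUE, posthoc = "tukey") {
  df <- data.frame(
    y = data[[response]],
    G = factor(data[[between]]),
    W = factor(data[[within]]),
    id = factor(data[[unit]]))
  df <- df[is.finite(df$y), ]
  empty <- setdiff(levels(df$W), unique(as.character(df$W)))
  if (length(empty)) {
    warning("dropping level(s) with no observations: ",
            paste(empty, collapse = ", "))
    df$W <- droplevels(df$W)
  }
  df$G <- droplevels(df$G); df$id <- droplevels(df$id)
  fit <- lmerTest::lmer(
    y ~ G * W + (1 | id), data = df, REML = TRUE,
    control = lme4::lmerControl(
      optimizer = "bobyqa",
      optCtrl = list(rhobeg = 0.2, rhoend = 1e-10)))
  an <- stats::anova(fit, type = 3)
  eff <- data.frame(
    term = c(between, within, paste(between, within, sep = ":")),
    df1 = an$NumDF, df2 = an$DenDF, F = an$`F value`, p = an$`Pr(>F)`)

  # epsilon from complete unit x level pairs, group x level means removed
  agg <- stats::aggregate(y ~ id + G + W, data = df, FUN = mean)
  cellMean <- stats::aggregate(y ~ G + W, data = agg, FUN = mean)
  agg$resid <- agg$y - cellMean$y[match(paste(agg$G, agg$W),
                                        paste(cellMean$G, cellMean$W))]
  wide <- stats::reshape(agg[, c("id", "W", "resid")], direction = "wide",
                         idvar = "id", timevar = "W")
  mat <- as.matrix(wide[, -1L, drop = FALSE])
  eps <- tryCatch(
    ggEpsilon(stats::cov(mat, use = "pairwise.complete.obs"),
              isCovariance = TRUE),
    error = function(e) NA_real_)
  if (ggCorrection && is.finite(eps)) {
    eff$epsilon <- c(NA, eps, eps)
    eff$p_gg <- eff$p
    for (r in 2:3)
      eff$p_gg[r] <- stats::pf(eff$F[r], eff$df1[r] * eps,
                               eff$df2[r] * eps, lower.tail = FALSE)
  }
  ph <- NULL
  if (posthoc != "none") {
    adj <- .posthocAdjust(posthoc)
    em <- emmeans::emmeans(fit, ~ G | W)
    ph <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                          adjust = adj))
  }
  list(effects = eff, posthoc = ph, epsilon = eps, model = fit)
}

#' Coefficient-of-variation table across fibers
#'
#' Per animal, the coefficient of variation (SD/mean) of the response over
#' its fibers; per group x week cell, the mean and SEM of those per-animal
#' CVs. Animals with fewer than two contributing fibers are excluded from a
#' cell.
#'
#' @param data long-format data.frame.
#' @param response,group,week,animal column names.
#' @return data.frame with `group`, `week`, `cv_mean`, `cv_sem`,
#'   `n_animals`.
#' @examples
#' d <- data.frame(group = "g", week = 1, animal = "a",
#'                 es = c(8, 10, 12))
#' cvTable(d, response = "es")$cv_mean # 0.2
#' @export
cvTable <- function(data, response = "es_da_nM", group = "group",
                    week = "week", animal = "animal") {
  df <- data.frame(y = data[[response]], g = data[[group]],
                   w = data[[week]], a = data[[animal]])
  df <- df[is.finite(df$y), ]
  perAnimal <- stats::aggregate(
    y ~ g + w + a, data = df,
    FUN = function(v) if (length(v) >= 2L) stats::sd(v) / mean(v) else
      NA_real_)
  perAnimal <- perAnimal[is.finite(perAnimal$y), ]
  out <- stats::aggregate(y ~ g + w, data = perAnimal, FUN = function(v)
    c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
      n = length(v)))
  data.frame(group = out$g, week = out$w,
             cv_mean = out$y[, "mean"], cv_sem = out$y[, "sem"],
             n_animals = as.integer(out$y[, "n"]))
}
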
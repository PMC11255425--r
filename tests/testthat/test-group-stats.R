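test_that("one-way ANOVA matches hand-computed sums of squares", {
  r <- anovaOneway(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r$F, 13.5)
  expect_equal(r$df, c(1, 4))

  same <- anovaOneway(rep(c(5, 6, 7), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(same$F, 0)

  expect_error(anovaOneway(c(1, 2, 3), c("a", "a", "b")), "at least 2")
})

test_that("Tukey flags only the pairs involving a shifted group", {
  set.seed(12)
  y <- c(rnorm(15), rnorm(15), rnorm(15, mean = 10))
  g <- rep(c("a", "b", "c"), each = 15)
  r <- anovaOneway(y, g)
  tk <- r$tukey
  hasC <- grepl("c", tk$comparison)
  expect_true(all(tk$`p adj`[hasC] < 0.001))
  expect_true(all(tk$`p adj`[!hasC] > 0.05))
})

test_that("Greenhouse-Geisser epsilon is 1 under compound symmetry", {
  S <- 0.4 * diag(4) + 0.6  # compound-symmetric covariance
  expect_equal(ggEpsilon(S, isCovariance = TRUE), 1)
  # sampled epsilon stays in its theoretical range
  set.seed(2)
  m <- matrix(rnorm(200), 50, 4) %*% matrix(runif(16), 4, 4)
  e <- ggEpsilon(m)
  expect_gte(e, 1 / 3)
  expect_lte(e, 1)
})

test_that("F statistics are invariant to affine rescaling of the response", {
  d <- generateCohort(cohortDesign(animalsPerGroup = 3L,
                                   fibersPerAnimal = 4L, dropoutP = 0),
                      seed = 2)
  d <- d[d$week == 1, ]
  r1 <- anovaTwoway(d, "es_da_nM", "group", "param", posthoc = "none")
  d$es_da_nM <- 3.2 * d$es_da_nM + 100
  r2 <- anovaTwoway(d, "es_da_nM", "group", "param", posthoc = "none")
  expect_equal(r1$effects$F, r2$effects$F, tolerance = 1e-9)
})

test_that("factorial ANOVA rejects empty cells outside the mixed path", {
  d <- data.frame(y = rnorm(12), A = rep(c("x", "y"), each = 6),
                  B = rep(c("u", "v"), 6))
  d <- d[!(d$A == "x" & d$B == "v"), ]
  expect_error(anovaTwoway(d, "y", "A", "B"), "empty cell")
})

test_that("the mixed model reduces to the split-plot ANOVA on balanced data", {
  d <- generateCohort(cohortDesign(animalsPerGroup = 3L,
                                   fibersPerAnimal = 6L, dropoutP = 0),
                      seed = 9)
  d <- d[d$param == "60Hz30p", ]
  mm <- mixedModelWeeks(d, posthoc = "none")
  tw <- anovaTwoway(d, "es_da_nM", "group", "week", subject = "fiber",
                    within = "week", ggCorrection = TRUE, posthoc = "none")
  expect_equal(mm$effects$F, tw$effects$F, tolerance = 1e-4)
  expect_equal(mm$effects$df1, tw$effects$df1)
  expect_lt(abs(mm$epsilon - tw$epsilon), 0.05)
})

test_that("the mixed model tolerates missing fiber-weeks and finds real week effects", {
  d <- generateCohort(cohortDesign(sensitizationSlope = 0.25,
                                   animalsPerGroup = 4L,
                                   fibersPerAnimal = 8L, dropoutP = 0.15),
                      seed = 30)
  d <- d[d$param == "60Hz60p", ]
  # true means rise across weeks by construction
  wk <- aggregate(es_da_nM ~ week, d, mean)
  expect_lt(wk$es_da_nM[1], wk$es_da_nM[4])
  mm <- mixedModelWeeks(d, posthoc = "sidak")
  pWeek <- mm$effects$p[mm$effects$term == "week"]
  expect_lt(pWeek, 0.05)
  expect_true(is.data.frame(mm$posthoc))
})

test_that("weeks without observations are dropped with a warning", {
  d <- generateCohort(cohortDesign(animalsPerGroup = 2L,
                                   fibersPerAnimal = 4L, dropoutP = 0),
                      seed = 4)
  d <- d[d$param == "60Hz30p", ]
  d$es_da_nM[d$week == 3] <- NA
  expect_warning(mm <- mixedModelWeeks(d, posthoc = "none"), "no observations")
  expect_equal(mm$effects$df1[mm$effects$term == "week"], 2)
})

test_that("CV tables follow the SD/mean definition", {
  d <- data.frame(group = "g", week = 1, animal = "a", es = c(8, 10, 12))
  expect_equal(cvTable(d, response = "es")$cv_mean, 0.2)

  # all fibers equal -> CV 0; single-fiber animals are excluded
  d2 <- data.frame(group = "g", week = 1,
                   animal = c("a", "a", "a", "b"),
                   es = c(5, 5, 5, 99))
  r <- cvTable(d2, response = "es")
  expect_equal(r$cv_mean, 0)
  expect_equal(r$n_animals, 1L)
})

test_that("the default cohort reproduces the week-1 fiber variability", {
  d <- generateCohort(cohortDesign(), seed = 5)
  r <- cvTable(d[d$param == "60Hz30p" & d$week == 1, ])
  expect_true(all(abs(r$cv_mean - 0.27) < 0.05))
})
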
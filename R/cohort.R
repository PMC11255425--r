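# Cohort-level synthesis: fiber-level ES DA / Tau tables for a groups x
# weeks x stimulation-parameter design with known effects, emulating the
# chronic study layout (two groups, 4 weekly sessions, 60 Hz 30p and 60p
# trains, 16 fibers per animal). Variability is multiplicative log-normal at
# three levels: animal, fiber (stable across weeks) and observation. The
# fiber-level dispersion defaults target a within-animal coefficient of
# variation of ~0.27, the week-1 value reported for chronically implanted
# arrays; fibers drop below threshold at random to produce the missingness
# a mixed model must tolerate.

#' Cohort design for the synthetic generator
#'
#' @param groups named numeric vector of group multipliers on ES DA (the
#'   default carries a female > male release effect).
#' @param animalsPerGroup animals per group.
#' @param fibersPerAnimal recording fibers per animal.
#' @param weeks number of weekly sessions.
#' @param params named numeric vector of stimulation-parameter multipliers.
#' @param baseEs grand-mean ES DA at week 1 for a unit group/parameter,
#'   nanomolar.
#' @param sensitizationSlope fractional ES DA increase per week (0.15 means
#'   +15% of the week-1 mean each week).
#' @param animalCV,fiberCV,residCV log-normal coefficients of variation at
#'   the animal, fiber and observation level. Fiber and observation noise
#'   combine to a within-animal CV of about 0.27 at the defaults.
#' @param baseTau mean clearance time constant, seconds.
#' @param tauGroupEffect named multipliers on Tau per group.
#' @param tauResidCV observation-level CV of Tau.
#' @param dropoutP probability a fiber is below threshold in a given week.
#' @return a design list for [generateCohort()].
#' @export
cohortDesign <- function(groups = c(male = 1, female = 1.3),
                         animalsPerGroup = 6L, fibersPerAnimal = 16L,
                         weeks = 4L,
                         params = c("60Hz30p" = 1, "60Hz60p" = 1.6),
                         baseEs = 500, sensitizationSlope = 0.15,
                         animalCV = 0.2, fiberCV = 0.25, residCV = 0.10,
                         baseTau = 2,
                         tauGroupEffect = c(male = 1, female = 1.2),
                         tauResidCV = 0.15, dropoutP = 0.1) {
  stopifnot(length(groups) >= 1L, !is.null(names(groups)),
            !is.null(names(params)))
  list(groups = groups, animalsPerGroup = as.integer(animalsPerGroup),
       fibersPerAnimal = as.integer(fibersPerAnimal),
       weeks = as.integer(weeks), params = params, baseEs = baseEs,
       sensitizationSlope = sensitizationSlope, animalCV = animalCV,
       fiberCV = fiberCV, residCV = residCV, baseTau = baseTau,
       tauGroupEffect = tauGroupEffect, tauResidCV = tauResidCV,
       dropoutP = dropoutP)
}

.rlnormCV <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic cohort table with known effects
#'
#' Produces the long fiber-level results table of a groups x weeks x
#' stimulation-parameter study:
#' `es = baseEs * group * param * (1 + slope*(week-1)) * animal * fiber *
#' noise`, with log-normal animal, fiber and observation factors, and Tau
#' generated analogously from its group multipliers. Rows where the fiber
#' fell below threshold that week have `present = FALSE` and `NA` values.
#' The true effect multipliers are attached as `attr(x, "truth")`.
#'
#' @param design a [cohortDesign()] list.
#' @param seed integer seed.
#' @return data.frame with columns `group`, `animal`, `fiber`, `week`,
#'   `param`, `es_da_nM`, `tau_s`, `present`.
#' @export
generateCohort <- function(design = cohortDesign(), seed = 1L) {
  d <- design
  set.seed(as.integer(seed))
  grid <- expand.grid(
    fiber = seq_len(d$fibersPerAnimal),
    animal = seq_len(d$animalsPerGroup),
    group = names(d$groups),
    week = seq_len(d$weeks),
    param = names(d$params),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$animal <- paste(grid$group, grid$animal, sep = "_a")
  grid$fiber <- paste(grid$animal, grid$fiber, sep = "_f")

  animals <- unique(grid$animal)
  fibers <- unique(grid$fiber)
  aEff <- stats::setNames(.rlnormCV(length(animals), d$animalCV), animals)
  fEff <- stats::setNames(.rlnormCV(length(fibers), d$fiberCV), fibers)
  fTau <- stats::setNames(.rlnormCV(length(fibers), d$fiberCV / 2), fibers)

  weekScale <- 1 + d$sensitizationSlope * (grid$week - 1)
  mu <- d$baseEs * d$groups[grid$group] * d$params[grid$param] *
    weekScale * aEff[grid$animal] * fEff[grid$fiber]
  grid$es_da_nM <- as.numeric(mu * .rlnormCV(nrow(grid), d$residCV))
  grid$tau_s <- as.numeric(d$baseTau * d$tauGroupEffect[grid$group] *
                             fTau[grid$fiber] *
                             .rlnormCV(nrow(grid), d$tauResidCV))

  # below-threshold dropout per fiber-week (shared across parameters)
  fw <- unique(grid[, c("fiber", "week")])
  fw$present <- stats::runif(nrow(fw)) >= d$dropoutP
  grid <- merge(grid, fw, by = c("fiber", "week"), sort = FALSE)
  grid$es_da_nM[!grid$present] <- NA_real_
  grid$tau_s[!grid$present] <- NA_real_

  grid <- grid[order(grid$group, grid$animal, grid$fiber, grid$week,
                     grid$param),
               c("group", "animal", "fiber", "week", "param",
                 "es_da_nM", "tau_s", "present")]
  rownames(grid) <- NULL
  attr(grid, "truth") <- d
  grid
}
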
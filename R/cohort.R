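#' Specification of a synthetic patient cohort
#'
#' Parameters of the cohort generator that stands in for the patient-level
#' table: covariate distributions (age, tumour diameter, grade, PR status,
#' axillary nodal category, systemic therapy, menopausal status, weeks
#' since last menstrual period, ER/PR staining percentages), a latent CPE
#' value whose mean is shifted by the covariates (confounding), and
#' invasive disease-free / overall survival times from an exponential
#' proportional-hazards model with per-tertile log hazard ratios.
#'
#' Defaults emulate the validation cohort the pipeline targets: median age
#' 48, median diameter 1.3 cm, grade mix skewed towards grade III, 84\% PR
#' positive, nodal categories 55/33/12\%, mostly endocrine +/- chemotherapy,
#' latent CPE ~ Normal(0.37, 0.10), a low-tertile event hazard of
#' 0.0025/month with 40\% of event hazard due to death, staggered-entry
#' censoring (exponential, rate 0.0079/month) and a 120-month
#' administrative horizon. Under the default hazard ratios (1, 0.84, 0.25)
#' these rates reproduce event fractions near 13\% (IDFS) and 5\% (OS).
#'
#' @slot nPatients cohort size (>= 3).
#' @slot covariateDistributions named list of distribution parameters; see
#'   \code{\link{cohortSpec}} for the entries and defaults.
#' @slot confoundingStrength scalar multiplying the covariate effects on
#'   the latent CPE (0 = no confounding).
#' @slot trueLogHr numeric(3): log hazard ratio of each tertile versus low
#'   (first element is the low tertile itself and must be 0).
#' @slot covariateLogHr named numeric: log-hazard effects of covariates
#'   (these, together with \code{confoundingStrength}, create confounding).
#' @slot baselineHazard low-tertile event (recurrence-or-death) hazard per
#'   month at covariate means.
#' @slot mortalityFraction fraction of the event hazard attributable to
#'   death (OS events are then a subset of IDFS events).
#' @slot censorRate exponential rate per month of independent (entry
#'   staggering / loss to follow-up) censoring.
#' @slot censorHorizonMonths administrative censoring time (> 0).
#' @slot missingRate MCAR missingness fraction applied independently to
#'   grade, diameter and nodal category, in [0,1).
#' @slot cpeMean,cpeSd mean and SD of the latent CPE distribution.
#' @slot seed RNG seed.
#' @seealso \code{\link{generateCohort}}
#' @export
setClass("CohortSpec",
  representation(
    nPatients              = "integer",
    covariateDistributions = "list",
    confoundingStrength    = "numeric",
    trueLogHr              = "numeric",
    covariateLogHr         = "numeric",
    baselineHazard         = "numeric",
    mortalityFraction      = "numeric",
    censorRate             = "numeric",
    censorHorizonMonths    = "numeric",
    missingRate            = "numeric",
    cpeMean                = "numeric",
    cpeSd                  = "numeric",
    seed                   = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nPatients < 3L) msg <- c(msg, "nPatients must be >= 3")
  if (length(object@trueLogHr) != 3L || object@trueLogHr[1] != 0)
    msg <- c(msg, "trueLogHr must be length 3 with first element 0 (low)")
  if (object@baselineHazard <= 0)
    msg <- c(msg, "baselineHazard must be positive")
  if (object@censorHorizonMonths <= 0)
    msg <- c(msg, "censorHorizonMonths must be positive")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0,1)")
  if (object@mortalityFraction <= 0 || object@mortalityFraction >= 1)
    msg <- c(msg, "mortalityFraction must lie in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Create a cohort specification
#'
#' @param nPatients cohort size.
#' @param covariateDistributions named list; recognised entries (with
#'   defaults): \code{ageMean = 49, ageSd = 10}, \code{diamMeanLog =
#'   log(1.3), diamSdLog = 0.64}, \code{gradeProbs = c(0.09, 0.37, 0.54)},
#'   \code{prPositive = 0.84}, \code{nodesProbs = c(0.55, 0.33, 0.12)},
#'   \code{therapyProbs = c(0.04, 0.30, 0.03, 0.63)} (none / endocrine /
#'   chemo / both), \code{lmpRecorded = 0.59}, \code{erPctAvailable =
#'   0.52}, \code{prPctAvailable = 0.51}.
#' @param confoundingStrength scalar; 0 removes all confounding.
#' @param trueLogHr numeric(3), log HR per tertile vs low (first element 0).
#' @param covariateLogHr log-hazard effects; default
#'   \code{c(ageZ = 0.2, diamZ = 0.25, grade3 = 0.5, nodes13 = 0.3,
#'   nodes4 = 0.7)}.
#' @param baselineHazard low-tertile event hazard per month.
#' @param mortalityFraction fraction of event hazard that is death.
#' @param censorRate independent censoring rate per month.
#' @param censorHorizonMonths administrative horizon.
#' @param missingRate MCAR missingness for grade/diameter/nodes.
#' @param cpeMean,cpeSd latent CPE distribution parameters.
#' @param seed integer RNG seed.
#' @return A validated \code{\linkS4class{CohortSpec}}.
#' @examples
#' spec <- cohortSpec(nPatients = 300, seed = 11)
#' @export
cohortSpec <- function(nPatients = 302L,
                       covariateDistributions = list(),
                       confoundingStrength = 1,
                       trueLogHr = c(0, log(0.84), log(0.25)),
                       covariateLogHr = c(ageZ = 0.2, diamZ = 0.25,
                                          grade3 = 0.5, nodes13 = 0.3,
                                          nodes4 = 0.7),
                       baselineHazard = 0.0025,
                       mortalityFraction = 0.4,
                       censorRate = 0.0079,
                       censorHorizonMonths = 120,
                       missingRate = 0.04,
                       cpeMean = 0.37, cpeSd = 0.10,
                       seed = 1L) {
  defaults <- list(ageMean = 49, ageSd = 10, diamMeanLog = log(1.3),
                   diamSdLog = 0.64, gradeProbs = c(0.09, 0.37, 0.54),
                   prPositive = 0.84, nodesProbs = c(0.55, 0.33, 0.12),
                   therapyProbs = c(0.04, 0.30, 0.03, 0.63),
                   lmpRecorded = 0.59, erPctAvailable = 0.52,
                   prPctAvailable = 0.51)
  defaults[names(covariateDistributions)] <- covariateDistributions
  new("CohortSpec",
      nPatients = as.integer(nPatients),
      covariateDistributions = defaults,
      confoundingStrength = confoundingStrength,
      trueLogHr = trueLogHr, covariateLogHr = covariateLogHr,
      baselineHazard = baselineHazard,
      mortalityFraction = mortalityFraction,
      censorRate = censorRate,
      censorHorizonMonths = censorHorizonMonths,
      missingRate = missingRate, cpeMean = cpeMean, cpeSd = cpeSd,
      seed = as.integer(seed))
}

#' Generate a synthetic patient cohort
#'
#' Draws covariates from the specified distributions, a latent CPE value
#' whose mean is shifted by (standardised) covariates when
#' \code{confoundingStrength > 0}, trichotomises CPE with
#' \code{\link{assignTertiles}}, and simulates recurrence and death times
#' from independent exponential distributions whose hazards carry both the
#' per-tertile log hazard ratio and the covariate log-hazard effects
#' (proportional hazards by construction). The IDFS time is the earlier of
#' recurrence and death; the OS time is death; both are censored by an
#' independent exponential time and the administrative horizon, so
#' observed OS events are a subset of IDFS events. Grade, diameter and
#' nodal category are then set missing completely at random at
#' \code{missingRate}.
#'
#' @param spec a \code{\linkS4class{CohortSpec}}.
#' @return data.frame with one row per patient; columns \code{patient_id,
#'   age_years, tumour_diameter_cm, grade, pr_status, nodes_cat, therapy,
#'   menopausal_status, weeks_since_lmp, er_pct, pr_pct, cpe, tertile,
#'   idfs_time_months, idfs_event, os_time_months, os_event,
#'   recurrence_site}.
#' @examples
#' head(generateCohort(cohortSpec(nPatients = 50, seed = 3)))
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  set.seed(spec@seed)
  n <- spec@nPatients
  cd <- spec@covariateDistributions

  age <- stats::rnorm(n, cd$ageMean, cd$ageSd)
  age <- pmin(pmax(age, 25), 90)
  diam <- stats::rlnorm(n, cd$diamMeanLog, cd$diamSdLog)
  grade <- sample(1:3, n, TRUE, prob = cd$gradeProbs)
  pr <- factor(ifelse(stats::runif(n) < cd$prPositive, "pos", "neg"),
               levels = c("neg", "pos"))
  nodes <- factor(sample(c("0", "1-3", "4+"), n, TRUE,
                         prob = cd$nodesProbs),
                  levels = c("0", "1-3", "4+"))
  therapy <- factor(sample(c("none", "endocrine", "chemo", "both"), n, TRUE,
                           prob = cd$therapyProbs),
                    levels = c("none", "endocrine", "chemo", "both"))

  # menopausal status follows age; weeks since LMP recorded for a subset
  # of premenopausal patients
  menop <- cut(age + stats::rnorm(n, 0, 3), c(-Inf, 48, 52, Inf),
               labels = c("pre", "peri", "post"))
  weeks <- rep(NA_integer_, n)
  pre <- which(menop == "pre" & stats::runif(n) < cd$lmpRecorded)
  weeks[pre] <- sample(1:4, length(pre), TRUE,
                       prob = c(0.3, 0.3, 0.25, 0.15))
  erPct <- ifelse(stats::runif(n) < cd$erPctAvailable,
                  round(100 * stats::rbeta(n, 9, 1.2)), NA_real_)
  prPct <- ifelse(stats::runif(n) < cd$prPctAvailable,
                  round(100 * stats::rbeta(n, 2, 1.2)), NA_real_)

  # latent CPE: mean shifted by covariates -> confounded tertiles.
  # younger, lower-grade, node-negative patients tend to higher CPE.
  ageZ <- (age - cd$ageMean) / cd$ageSd
  diamZ <- (log(diam) - cd$diamMeanLog) / cd$diamSdLog
  confounder <- -0.5 * ageZ - 0.35 * (grade == 3) -
    0.25 * (nodes == "1-3") - 0.45 * (nodes == "4+") - 0.15 * diamZ
  cpe <- spec@cpeMean +
    spec@confoundingStrength * 0.05 * confounder +
    stats::rnorm(n, 0, spec@cpeSd)
  tertile <- assignTertiles(cpe)

  # proportional-hazards event times: recurrence and death hazards share
  # the tertile and covariate effects
  b <- spec@covariateLogHr
  lp <- spec@trueLogHr[as.integer(tertile)] +
    b["ageZ"] * ageZ + b["diamZ"] * diamZ + b["grade3"] * (grade == 3) +
    b["nodes13"] * (nodes == "1-3") + b["nodes4"] * (nodes == "4+")
  rateRec <- spec@baselineHazard * (1 - spec@mortalityFraction) * exp(lp)
  rateDeath <- spec@baselineHazard * spec@mortalityFraction * exp(lp)
  tRec <- stats::rexp(n, rateRec)
  tDeath <- stats::rexp(n, rateDeath)
  tCens <- if (spec@censorRate > 0)
    pmin(stats::rexp(n, spec@censorRate), spec@censorHorizonMonths)
  else rep(spec@censorHorizonMonths, n)  # administrative censoring only

  tIdfs <- pmin(tRec, tDeath)
  idfsEvent <- as.integer(tIdfs <= tCens)
  idfsTime <- pmin(tIdfs, tCens)
  osEvent <- as.integer(tDeath <= tCens)
  osTime <- pmin(tDeath, tCens)
  site <- rep(NA_character_, n)
  rec <- idfsEvent == 1 & tRec < tDeath
  site[rec] <- sample(c("local", "regional", "distant"), sum(rec), TRUE,
                      prob = c(0.16, 0.19, 0.65))

  out <- data.frame(
    patient_id = seq_len(n),
    age_years = age, tumour_diameter_cm = diam, grade = grade,
    pr_status = pr, nodes_cat = nodes, therapy = therapy,
    menopausal_status = menop, weeks_since_lmp = weeks,
    er_pct = erPct, pr_pct = prPct,
    cpe = cpe, tertile = tertile,
    idfs_time_months = idfsTime, idfs_event = idfsEvent,
    os_time_months = osTime, os_event = osEvent,
    recurrence_site = site,
    stringsAsFactors = FALSE)

  if (spec@missingRate > 0) {
    for (v in c("grade", "tumour_diameter_cm", "nodes_cat"))
      out[[v]][stats::runif(n) < spec@missingRate] <- NA
  }
  out
}
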
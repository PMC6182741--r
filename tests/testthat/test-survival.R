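test_that("administrative censoring recodes events beyond the horizon", {
  d <- survFixture(30, seed = 2)
  d$idfs_time_months[1] <- 130; d$idfs_event[1] <- 1L
  d$os_time_months[1] <- 130; d$os_event[1] <- 1L
  d$idfs_time_months[2] <- 119; d$idfs_event[2] <- 1L
  out <- administrativeCensor(d, 120)
  expect_equal(out$idfs_time_months[1], 120)
  expect_equal(out$idfs_event[1], 0L)
  expect_equal(out$os_event[1], 0L)
  expect_equal(out$idfs_time_months[2], 119)
  expect_equal(out$idfs_event[2], 1L)
  # all-censored input unchanged
  d2 <- survFixture(20, seed = 3)
  d2$idfs_event <- 0L; d2$os_event <- 0L
  expect_equal(administrativeCensor(d2), d2)
})

test_that("multiple imputation preserves complete-data structure", {
  full <- generateCohort(cohortSpec(nPatients = 500, missingRate = 0,
                                    seed = 21))
  # missing_rate = 0: all m datasets identical to the input
  imps <- imputeMissing(full, m = 3, seed = 1)
  expect_length(imps, 3)
  expect_identical(imps[[1]], full)
  expect_identical(imps[[2]], full)
  expect_warning(imputeMissing(full, m = 1, seed = 1), "between-imputation")

  # MCAR 10%: pooled means within 2 SE of the complete-data means
  set.seed(22)
  holed <- full
  for (v in c("grade", "tumour_diameter_cm", "nodes_cat"))
    holed[[v]][sample(500, 50)] <- NA
  imps <- imputeMissing(holed, m = 10, seed = 2)
  expect_false(anyNA(imps[[5]][c("grade", "tumour_diameter_cm",
                                 "nodes_cat")]))
  pooledDiam <- mean(sapply(imps, function(d) mean(d$tumour_diameter_cm)))
  seDiam <- sd(full$tumour_diameter_cm) / sqrt(500)
  expect_lt(abs(pooledDiam - mean(full$tumour_diameter_cm)), 2 * seDiam)
  pooledGrade <- mean(sapply(imps, function(d) mean(d$grade == 3)))
  seGrade <- sd(full$grade == 3) / sqrt(500)
  expect_lt(abs(pooledGrade - mean(full$grade == 3)), 2 * seGrade)

  allMissing <- holed; allMissing$grade <- NA
  expect_error(imputeMissing(allMissing, m = 2), "all values")
})

test_that("propensity probabilities behave on null and confounded cohorts", {
  # null cohort: fitted probabilities near 1/3 and summing to 1
  d <- generateCohort(cohortSpec(nPatients = 3000, confoundingStrength = 0,
                                 missingRate = 0, seed = 23))
  pf <- fitPropensity(d)
  expect_equal(unname(rowSums(pf@probabilities)), rep(1, 3000),
               tolerance = 1e-9)
  # near 1/3 on average; the spline tails are noisier than the bulk
  expect_lt(mean(abs(pf@probabilities - 1 / 3)), 0.03)
  expect_lt(quantile(abs(pf@probabilities - 1 / 3), 0.95, names = FALSE),
            0.1)

  # strong single confounder: P(high) monotone in it
  set.seed(24)
  d2 <- generateCohort(cohortSpec(nPatients = 2000, confoundingStrength = 4,
                                  missingRate = 0, seed = 25))
  pf2 <- fitPropensity(d2)
  pHigh <- pf2@probabilities[, "high"]
  ageBins <- cut(d2$age_years, quantile(d2$age_years, 0:4 / 4),
                 include.lowest = TRUE)
  binMeans <- tapply(pHigh, ageBins, mean)
  expect_true(all(diff(binMeans) < 0))  # older -> lower CPE tertile

  dNA <- d2; dNA$grade[1] <- NA
  expect_error(fitPropensity(dNA), "complete covariates")
})

test_that("stabilised IPW weights balance confounded covariates", {
  d <- generateCohort(cohortSpec(nPatients = 2500, confoundingStrength = 0,
                                 missingRate = 0, seed = 26))
  pf <- fitPropensity(d)
  w <- computeIpwWeights(pf, d)
  # null cohort with equal tertiles: stabilised weights all near 1
  expect_lt(max(abs(w - 1)), 0.35)
  expect_lt(abs(sum(w) - nrow(d)) / nrow(d), 0.05)

  d2 <- generateCohort(cohortSpec(nPatients = 2500, confoundingStrength = 3,
                                  missingRate = 0, seed = 27))
  pf2 <- fitPropensity(d2)
  w2 <- computeIpwWeights(pf2, d2)
  expect_lt(abs(sum(w2) - nrow(d2)) / nrow(d2), 0.05)
  # weighting shrinks the standardised mean difference of the confounder
  high <- d2$tertile == "high"
  expect_lt(abs(cpemri:::smd(d2$age_years, high, w2)),
            abs(cpemri:::smd(d2$age_years, high)))
})

test_that("weighted Cox reduces to unweighted Cox at unit weights", {
  d <- survFixture(200, seed = 28)
  fit <- fitWeightedCox(d, rep(1, 200), "idfs")
  ref <- survival::coxph(
    survival::Surv(idfs_time_months, idfs_event) ~ tertile, data = d)
  expect_equal(hazardRatios(fit)$logHr, as.vector(coef(ref)),
               tolerance = 1e-6)
  expect_true(all(hazardRatios(fit)$lo <= hazardRatios(fit)$hr))
  expect_true(all(hazardRatios(fit)$hr <= hazardRatios(fit)$hi))

  noEv <- d; noEv$idfs_event <- 0L
  expect_error(fitWeightedCox(noEv, rep(1, 200), "idfs"), "no events")
  refEv <- d; refEv$idfs_event[refEv$tertile == "low"] <- 0L
  expect_error(fitWeightedCox(refEv, rep(1, 200), "idfs"), "reference")
})

test_that("weighted Cox recovers a true HR of 0.25 at n = 5000", {
  d <- generateCohort(cohortSpec(nPatients = 5000, confoundingStrength = 0,
                                 covariateLogHr = c(ageZ = 0, diamZ = 0,
                                                    grade3 = 0, nodes13 = 0,
                                                    nodes4 = 0),
                                 trueLogHr = c(0, log(0.84), log(0.25)),
                                 missingRate = 0, seed = 29))
  fit <- fitWeightedCox(d, rep(1, 5000), "idfs")
  hrHigh <- hazardRatios(fit)$hr[hazardRatios(fit)$tertile == "high"]
  expect_gt(hrHigh, 0.20)
  expect_lt(hrHigh, 0.31)
})

test_that("Rubin pooling matches hand computation and degenerate cases", {
  d <- survFixture(150, seed = 30)
  fit <- fitWeightedCox(d, rep(1, 150), "idfs")
  # pooling identical fits returns the common fit
  pooled <- poolFits(list(fit, fit, fit))
  expect_equal(hazardRatios(pooled)$hr, hazardRatios(fit)$hr)
  expect_equal(hazardRatios(pooled)$se, hazardRatios(fit)$se)
  expect_equal(trendTest(pooled)$p, trendTest(fit)$p, tolerance = 1e-12)
  expect_true(pooled@pooled)
  expect_true(all(hazardRatios(pooled)$hr > 0))

  # m = 2 with known log-HRs 0 and 0.2 and known SEs: hand-computed Rubin
  mkFit <- function(logHr, se) {
    f <- fit
    f@table$logHr <- logHr; f@table$se <- se
    f@table$hr <- exp(logHr)
    f@table$lo <- exp(logHr - 1.96 * se)
    f@table$hi <- exp(logHr + 1.96 * se)
    f
  }
  p2 <- poolFits(list(mkFit(c(0, 0), c(0.10, 0.10)),
                      mkFit(c(0.2, 0.2), c(0.12, 0.12))))
  qbar <- mean(c(0, 0.2))
  W <- mean(c(0.10, 0.12)^2)
  B <- var(c(0, 0.2))
  Tv <- W + (1 + 1 / 2) * B
  expect_equal(hazardRatios(p2)$logHr, rep(qbar, 2))
  expect_equal(hazardRatios(p2)$se, rep(sqrt(Tv), 2), tolerance = 1e-12)
  df <- (2 - 1) * (1 + W / ((1 + 1 / 2) * B))^2
  expect_equal(hazardRatios(p2)$p,
               rep(2 * pt(-abs(qbar / sqrt(Tv)), df), 2), tolerance = 1e-12)
})

test_that("IPW-adjusted HR beats the crude HR on confounded cohorts", {
  # compact version of the end-to-end recovery property (20 replicates)
  res <- t(sapply(1:20, function(i) {
    d <- generateCohort(cohortSpec(nPatients = 2000, missingRate = 0,
                                   confoundingStrength = 3,
                                   seed = 3000 + i))
    crude <- exp(coef(survival::coxph(
      survival::Surv(idfs_time_months, idfs_event) ~ tertile,
      data = d)))[2]
    ipw <- hazardRatios(ipwSurvival(d, "idfs"))
    c(crude = unname(crude), ipw = ipw$hr[ipw$tertile == "high"])
  }))
  closer <- abs(log(res[, "ipw"]) - log(0.25)) <
    abs(log(res[, "crude"]) - log(0.25))
  expect_gte(mean(closer), 0.9)
  expect_lt(abs(median(res[, "ipw"]) - 0.25), 0.05)
})
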
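test_that("noise-free phantom has exact kinetics and compartment geometry", {
  ph <- smallPhantom(noiseSd = 0, biasFieldAmplitude = 0, motionMm = 0,
                     kineticParams = list(uptake = 0.6, late = 0.4))
  par <- ph$truth@parenchymaMask
  s1 <- ph$series@fatSat[[2]][par]
  s3 <- ph$series@fatSat[[4]][par]
  expect_equal(unique(round((s3 - s1) / s1, 12)), 0.4)

  # parenchyma voxel count matches the requested fraction (+-1 per breast)
  ph2 <- smallPhantom(parenchymaFraction = 0.2, noiseSd = 0)
  expect_lte(abs(sum(ph2$truth@parenchymaMask) -
                 0.2 * sum(ph2$truth@breastMask)), 2)

  # fat bright and non-enhancing; masks disjoint; bias strictly positive
  expect_gt(min(ph$series@nonFatSat[ph$truth@fatMask]),
            max(ph$series@nonFatSat[par]))
  fatCurve <- sapply(ph$series@fatSat, function(v)
    mean(v[ph$truth@fatMask]))
  expect_equal(diff(fatCurve), rep(0, 3), tolerance = 1e-12)
  expect_false(any(ph$truth@fatMask & par))
  expect_true(all(ph$truth@trueBiasField > 0))
})

test_that("phantom generation is deterministic in the seed", {
  a <- smallPhantom(seed = 42)
  b <- smallPhantom(seed = 42)
  expect_identical(a$series@fatSat, b$series@fatSat)
  expect_identical(a$series@nonFatSat, b$series@nonFatSat)
  expect_identical(a$truth@parenchymaMask, b$truth@parenchymaMask)
  c <- smallPhantom(seed = 43)
  expect_false(identical(a$series@nonFatSat, c$series@nonFatSat))
})

test_that("phantom spec validation rejects bad parameters", {
  expect_error(phantomSpec(parenchymaFraction = 0), "parenchymaFraction")
  expect_error(phantomSpec(noiseSd = -1), ">= 0")
  expect_error(phantomSpec(kineticParams = list(uptake = 0.5)), "late")
})

test_that("cohort generation respects its spec contracts", {
  spec <- cohortSpec(nPatients = 400, missingRate = 0, seed = 5)
  d <- generateCohort(spec)
  expect_equal(nrow(d), 400)
  # all times bounded by the administrative horizon
  expect_true(all(d$idfs_time_months <= 120))
  expect_true(all(d$os_time_months <= 120))
  # OS events are a subset of IDFS events, at equal or later time
  expect_true(all(d$idfs_event[d$os_event == 1] == 1))
  expect_true(all(d$idfs_time_months <= d$os_time_months + 1e-12))
  # missing_rate = 0 leaves nothing missing
  expect_false(anyNA(d[c("grade", "tumour_diameter_cm", "nodes_cat")]))
  # missingness injected at the requested rate (MCAR, so ~4%)
  d2 <- generateCohort(cohortSpec(nPatients = 3000, missingRate = 0.1,
                                  seed = 6))
  expect_gt(mean(is.na(d2$grade)), 0.07)
  expect_lt(mean(is.na(d2$grade)), 0.13)
  expect_error(cohortSpec(nPatients = 2), "nPatients")
  # determinism
  expect_identical(generateCohort(spec), generateCohort(spec))
})

test_that("null cohorts have equal event proportions across tertiles", {
  d <- generateCohort(cohortSpec(nPatients = 3000, trueLogHr = c(0, 0, 0),
                                 confoundingStrength = 0,
                                 covariateLogHr = c(ageZ = 0, diamZ = 0,
                                                    grade3 = 0, nodes13 = 0,
                                                    nodes4 = 0),
                                 missingRate = 0, seed = 8))
  prop <- tapply(d$idfs_event, d$tertile, mean)
  # binomial error at n = 1000 per group: 3 * SE(diff) is about 0.05
  expect_lt(max(prop) - min(prop), 0.05)
})

test_that("unconfounded covariates are balanced across latent tertiles", {
  d <- generateCohort(cohortSpec(nPatients = 6000, confoundingStrength = 0,
                                 missingRate = 0, seed = 9))
  ageMeans <- tapply(d$age_years, d$tertile, mean)
  expect_lt(max(ageMeans) - min(ageMeans), 1.2)  # ~3 SE at n = 2000
  gradeProp <- tapply(d$grade == 3, d$tertile, mean)
  expect_lt(max(gradeProp) - min(gradeProp), 0.05)
})

test_that("simulated hazards reproduce the specified hazard ratios", {
  d <- generateCohort(cohortSpec(nPatients = 10000, confoundingStrength = 0,
                                 covariateLogHr = c(ageZ = 0, diamZ = 0,
                                                    grade3 = 0, nodes13 = 0,
                                                    nodes4 = 0),
                                 censorRate = 0, missingRate = 0,
                                 trueLogHr = c(0, log(0.84), log(0.25)),
                                 seed = 10))
  fit <- survival::coxph(
    survival::Surv(idfs_time_months, idfs_event) ~ tertile, data = d)
  hr <- exp(coef(fit))
  expect_lt(abs(hr[1] - 0.84) / 0.84, 0.10)
  expect_lt(abs(hr[2] - 0.25) / 0.25, 0.10)
})
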
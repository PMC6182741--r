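emap <- function(values) {
  new("EnhancementMap", values = as.numeric(values),
      voxels = seq_along(values), dim = c(length(values), 1L, 1L))
}

test_that("enhancement map implements (S_last - S_first) / S_first", {
  d <- c(4, 4, 2)
  mk <- function(pre, s1, s2, s3) {
    new("DceSeries", nonFatSat = array(1, d),
        fatSat = list(array(pre, d), array(s1, d), array(s2, d),
                      array(s3, d)),
        voxelSize = c(1, 1, 1), laterality = "left", registered = TRUE)
  }
  m <- new("VoxelMask", mask = array(TRUE, d), side = "right",
           tissue = "parenchyma", eroded = TRUE, voxelSize = c(1, 1, 1))
  expect_equal(unique(computeEnhancementMap(mk(80, 100, 120, 150), m)@values),
               0.5)
  expect_equal(unique(computeEnhancementMap(mk(80, 100, 100, 100), m)@values),
               0)
  expect_equal(unique(computeEnhancementMap(mk(80, 200, 180, 150), m)@values),
               -0.25)
  # non-positive first post-contrast signal: error by default, exclude on
  # request
  bad <- mk(80, 100, 120, 150)
  bad@fatSat[[2]][1, 1, 1] <- 0
  expect_error(computeEnhancementMap(bad, m), "non-positive")
  ex <- computeEnhancementMap(bad, m, onNonPositive = "exclude")
  expect_equal(length(ex@values), prod(d) - 1)
  # unregistered series refused
  un <- mk(80, 100, 120, 150); un@registered <- FALSE
  expect_error(computeEnhancementMap(un, m), "registered")
})

test_that("CPE equals the mean of the top decile", {
  expect_equal(cpeValue(computeCpe(emap(1:100))), 95.5)
  expect_equal(computeCpe(emap(1:100))@p90, quantile(1:100, 0.9,
                                                     names = FALSE))
  expect_equal(cpeValue(computeCpe(emap(rep(0.4, 50)))), 0.4)
  expect_error(computeCpe(emap(1:9)), "at least 10")

  # brute-force oracle equivalence on random maps of varying size
  set.seed(11)
  for (i in 1:50) {
    v <- rnorm(sample(10:500, 1))
    expect_equal(cpeValue(computeCpe(emap(v))), bruteCpe(v),
                 tolerance = 1e-12)
  }
})

test_that("CPE is scale-invariant and monotone in S_last", {
  d <- c(5, 5, 4)
  set.seed(12)
  s1 <- array(runif(prod(d), 80, 120), d)
  s3 <- array(runif(prod(d), 100, 200), d)
  mk <- function(a, b) new("DceSeries", nonFatSat = array(1, d),
    fatSat = list(array(50, d), a, (a + b) / 2, b),
    voxelSize = c(1, 1, 1), laterality = "left", registered = TRUE)
  m <- new("VoxelMask", mask = array(TRUE, d), side = "right",
           tissue = "parenchyma", eroded = TRUE, voxelSize = c(1, 1, 1))
  base <- cpeValue(computeCpe(computeEnhancementMap(mk(s1, s3), m)))
  for (c in c(0.3, 7)) {
    scaled <- cpeValue(computeCpe(computeEnhancementMap(
      mk(c * s1, c * s3), m)))
    expect_equal(scaled, base, tolerance = 1e-12)
  }
  # raising any voxel's S_last never decreases CPE
  s3up <- s3; s3up[2, 3, 1] <- s3up[2, 3, 1] * 3
  up <- cpeValue(computeCpe(computeEnhancementMap(mk(s1, s3up), m)))
  expect_gte(up, base)
  # cpe >= median >= min of the enhancement values
  vals <- computeEnhancementMap(mk(s1, s3), m)@values
  expect_gte(base, median(vals))
  expect_gte(median(vals), min(vals))
})

test_that("tertile assignment gives equal groups with outer-first remainder", {
  # n = 302 reproduces the 101/100/101 split
  set.seed(13)
  t302 <- table(assignTertiles(rnorm(302)))
  expect_equal(as.vector(t302), c(101, 100, 101))
  expect_equal(as.vector(table(assignTertiles(rnorm(301)))), c(101, 100, 100))
  expect_equal(as.vector(table(assignTertiles(rnorm(300)))), c(100, 100, 100))

  expect_equal(as.character(assignTertiles(c(1, 2, 3))),
               c("low", "intermediate", "high"))
  expect_equal(as.character(assignTertiles(c(3, 1, 2))),
               c("high", "low", "intermediate"))
  expect_error(assignTertiles(c(1, 2)), "at least 3")

  # n = 9 distinct values: boundaries at ranks 3 and 6 (brute-force oracle)
  x <- sample(9)
  expect_equal(as.character(assignTertiles(x)), bruteTertiles(x))

  # permutation equivariance and rank-dependence only
  y <- rnorm(40)
  perm <- sample(40)
  expect_equal(as.character(assignTertiles(y))[perm],
               as.character(assignTertiles(y[perm])))
  expect_equal(assignTertiles(y), assignTertiles(rank(y)))

  # boundary ties broken by stable original order
  z <- c(1, 2, 2, 2, 5, 6)  # tie spans the low/intermediate boundary
  expect_equal(as.character(assignTertiles(z)),
               c("low", "low", "intermediate", "intermediate",
                 "high", "high"))
})
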
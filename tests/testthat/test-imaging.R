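test_that("bias-free phantom yields a flat estimated field", {
  ph <- smallPhantom(noiseSd = 0, biasFieldAmplitude = 0)
  bf <- correctBiasField(ph$series@nonFatSat)
  expect_lt(max(abs(bf$field - 1)), 0.02)
  # constant image: corrected equals input up to global scale
  const <- array(500, c(16, 16, 6))
  bc <- correctBiasField(const)
  expect_equal(bc$corrected / const, array(1, dim(const)), tolerance = 1e-8)
  expect_error(correctBiasField(array(0, c(8, 8, 4))), "positive")
})

test_that("a known smooth bias field is recovered inside the breast", {
  ph <- smallPhantom(noiseSd = 5, biasFieldAmplitude = 0.3, seed = 2)
  bf <- correctBiasField(ph$series@nonFatSat)
  br <- ph$truth@breastMask
  expect_gt(cor(bf$field[br], ph$truth@trueBiasField[br]), 0.95)
})

test_that("breast segmentation recovers both breasts and excludes the chest wall", {
  ph <- smallPhantom(seed = 3, gridShape = c(48, 48, 14))
  bf <- correctBiasField(ph$series@nonFatSat)
  b <- segmentBreast(ph$series, volume = bf$corrected)
  combined <- maskArray(b$left) | maskArray(b$right)
  expect_gte(diceCoef(combined, ph$truth@breastMask), 0.90)
  expect_false(any(maskArray(b$left) & maskArray(b$right)))
  expect_error(segmentBreast(
    new("DceSeries", nonFatSat = array(0, c(16, 16, 4)),
        fatSat = rep(list(array(0, c(16, 16, 4))), 4),
        voxelSize = c(1, 1, 1), laterality = "left")),
    "segmentation failed")
})

test_that("parenchyma segmentation finds the fibroglandular compartment", {
  ph <- smallPhantom(seed = 4, gridShape = c(48, 48, 14))
  bf <- correctBiasField(ph$series@nonFatSat)
  b <- segmentBreast(ph$series, volume = bf$corrected)
  contra <- setdiff(c("left", "right"), ph$series@laterality)
  p <- segmentParenchyma(ph$series, b[[contra]], volume = bf$corrected)
  gt <- ph$truth@parenchymaMask & maskArray(b[[contra]])
  expect_gte(diceCoef(maskArray(p), gt), 0.85)
  # never intersects the ipsilateral breast
  expect_false(any(maskArray(p) & maskArray(b[[ph$series@laterality]])))
  # refuses the ipsilateral mask
  expect_error(segmentParenchyma(ph$series, b[[ph$series@laterality]]),
               "contralateral")

  # recovered parenchyma fractions are ordered with the true fractions
  frac <- sapply(c(0.1, 0.4), function(f) {
    phf <- smallPhantom(parenchymaFraction = f, seed = 5)
    bff <- correctBiasField(phf$series@nonFatSat)
    bb <- segmentBreast(phf$series, volume = bff$corrected)
    pp <- segmentParenchyma(phf$series, bb$right, volume = bff$corrected)
    sum(maskArray(pp)) / sum(maskArray(bb$right))
  })
  expect_lt(frac[1], frac[2])
})

test_that("in-plane erosion follows 3x3 slice-wise morphology", {
  d <- c(9, 9, 3)
  m <- array(FALSE, d); m[3:7, 3:7, 2] <- TRUE    # 5x5 square, one slice
  vm <- new("VoxelMask", mask = m, side = "right", tissue = "parenchyma",
            voxelSize = c(1, 1, 1))
  e1 <- erodeInplane(vm)
  expect_equal(sum(maskArray(e1)), 9)             # 3x3 survives
  expect_true(all(which(maskArray(e1)[, , 2], arr.ind = TRUE) >= 4))
  expect_true(e1@eroded)
  # single voxel is removed; erosion twice strictly shrinks further
  m2 <- array(FALSE, d); m2[5, 5, 1] <- TRUE
  vm2 <- new("VoxelMask", mask = m2, side = "right", tissue = "parenchyma",
             voxelSize = c(1, 1, 1))
  expect_equal(sum(maskArray(erodeInplane(vm2))), 0)
  e2 <- erodeInplane(e1)
  expect_lt(sum(maskArray(e2)), sum(maskArray(e1)))
  # erosion never crosses slices
  m3 <- array(FALSE, d); m3[3:7, 3:7, ] <- TRUE
  vm3 <- new("VoxelMask", mask = m3, side = "right", tissue = "parenchyma",
             voxelSize = c(1, 1, 1))
  e3 <- erodeInplane(vm3)
  expect_equal(sum(maskArray(e3)[, , 1]), 9)      # edge slice keeps its 3x3
})

test_that("registration recovers applied translations to subvoxel accuracy", {
  # identity case: recovered displacement below 0.1 voxel
  ph0 <- smallPhantom(noiseSd = 5, motionMm = 0, seed = 6)
  reg0 <- suppressMessages(registerSeries(ph0$series))
  for (k in 2:4)
    expect_lt(max(abs(reg0@transforms[[k]] / ph0$series@voxelSize)), 0.1)

  # known 2 mm translations recovered within 0.5 mm
  ph <- smallPhantom(noiseSd = 5, motionMm = 2, seed = 7,
                     gridShape = c(48, 48, 14))
  reg <- suppressMessages(registerSeries(ph$series))
  for (k in 2:4) {
    err <- sqrt(sum((ph$truth@motionMm[k, ] + reg@transforms[[k]])^2))
    expect_lt(err, 0.5)
  }
  expect_true(reg@registered)

  # idempotent: re-registering moves volumes by less than the noise level
  reg2 <- suppressMessages(registerSeries(reg))
  for (k in 2:4) {
    expect_lt(sqrt(sum(reg2@transforms[[k]]^2)), 0.2)
    expect_lt(stats::sd(reg2@fatSat[[k]] - reg@fatSat[[k]]), 5)
  }
})

test_that("mask pipeline is monotone: eroded parenchyma within breast", {
  ph <- smallPhantom(seed = 8)
  bf <- correctBiasField(ph$series@nonFatSat)
  b <- segmentBreast(ph$series, volume = bf$corrected)
  p <- segmentParenchyma(ph$series, b$right, volume = bf$corrected)
  pe <- erodeInplane(p)
  expect_true(all(maskArray(pe) <= maskArray(p)))
  expect_true(all(maskArray(p) <= maskArray(b$right)))
})
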
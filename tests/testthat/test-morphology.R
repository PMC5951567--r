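test_that("location features: carina offset, equivariance, known centroid", {
  ph <- generatePhantom(phantomSpec(baseRadius = 6), seed = 9)
  ctr <- locationFeatures(ph@mask, carina = ph@carina)$centroid
  # carina placed at the centroid gives zero vertical offset
  lf0 <- locationFeatures(ph@mask, carina = ctr)
  expect_equal(lf0$offsetCarinaZ, 0)
  # phantom centroid is at the world origin within half a voxel
  expect_lt(max(abs(ctr)), max(spacingMm(ph@mask)) / 2)
  # translating the grid origin moves the centroid with it and leaves the
  # carina offset unchanged when the carina moves too
  m2 <- noduleMask(voxelData(ph@mask), spacing = spacingMm(ph@mask),
                   origin = originMm(ph@mask) + c(0, 0, 5))
  lf2 <- locationFeatures(m2, carina = ph@carina + c(0, 0, 5))
  expect_equal(lf2$centroid[3], ctr[3] + 5)
  expect_equal(lf2$offsetCarinaZ,
               locationFeatures(ph@mask, ph@carina)$offsetCarinaZ)
  expect_true(lf2$locationCode %in% 1:6)
  expect_error(locationFeatures(noduleMask(array(FALSE, c(3, 3, 3))), c(0, 0, 0)),
               "empty")
})

test_that("size features: single voxel, spacing scaling, sphere area", {
  one <- array(FALSE, c(5, 5, 5))
  one[3, 3, 3] <- TRUE
  sf <- suppressWarnings(sizeFeatures(noduleMask(one)))
  expect_equal(sf$volumeMm3, 1)
  m <- noduleMask(one, spacing = c(1, 1, 2))
  expect_equal(sizeFeatures(m)$volumeMm3, 2)
  fx <- sphereFixture()
  sf <- sizeFeatures(fx$phantom@mask, fx$mesh)
  expect_lt(abs(sf$surfaceAreaMm2 / (4 * pi * 100) - 1), 0.03)
})

test_that("sphere shape features match the analytic ball", {
  fx <- sphereFixture()
  shp <- shapeFeatures(fx$phantom@mask, fx$mesh)
  expect_gte(shp$sphericity, 0.97)
  expect_lte(shp$sphericity, 1 + 1e-9)
  expect_lt(abs(shp$sphereFitFactor - 1), 0.1)
  expect_lt(abs(shp$estimatedRadius / 10 - 1), 0.02)
  expect_lt(abs(shp$elongation), 0.05)
  expect_lt(abs(shp$flatness), 0.05)
  # algebraic identity between the two sphericity-type features
  expect_equal(shp$sphereFitFactor * shp$sphericity^3, 1, tolerance = 1e-9)
  expect_true(shp$brickX >= shp$brickY && shp$brickY >= shp$brickZ)
})

test_that("ellipsoid axis ratios are recovered on the PCA brick", {
  ph <- generatePhantom(phantomSpec(baseRadius = 20,
                                    axisRatios = c(1, 0.5, 0.25)), seed = 13)
  shp <- shapeFeatures(ph@mask)
  expect_lt(abs(shp$elongation - log(0.5)), 0.08)
  expect_lt(abs(shp$flatness - log(0.25)), 0.08)
  expect_true(shp$elongation <= 0 && shp$flatness <= 0)
})

test_that("shape features are invariant to translation and axis relabeling", {
  ph <- generatePhantom(phantomSpec(baseRadius = 6,
                                    axisRatios = c(1, 0.8, 0.6)), seed = 21)
  shp <- shapeFeatures(ph@mask)
  moved <- noduleMask(voxelData(ph@mask), spacing = spacingMm(ph@mask),
                      origin = originMm(ph@mask) + c(7, -3, 11))
  shp2 <- shapeFeatures(moved)
  perm <- noduleMask(aperm(voxelData(ph@mask), c(3, 1, 2)),
                     spacing = spacingMm(ph@mask)[c(3, 1, 2)],
                     origin = originMm(ph@mask)[c(3, 1, 2)])
  shp3 <- shapeFeatures(perm)
  for (f in c("volumeMm3", "elongation", "flatness")) {
    expect_equal(shp2[[f]], shp[[f]], tolerance = 1e-6)
    expect_equal(shp3[[f]], shp[[f]], tolerance = 0.02)
  }
})

test_that("density features: moments, entropy, degenerate inputs", {
  m <- array(TRUE, c(4, 4, 4))
  vol <- voxelVolume(array(-200, c(4, 4, 4)))
  den <- densityFeatures(vol, noduleMask(m))
  expect_equal(den$huMean, -200)
  expect_equal(den$huVariance, 0)
  expect_equal(den$huSkew, 0)
  expect_equal(den$huEntropy, 0)
  # two equiprobable HU values: 1 bit of entropy, known variance
  half <- array(rep(c(-100, -300), each = 32), c(4, 4, 4))
  den2 <- densityFeatures(voxelVolume(half), noduleMask(m))
  expect_equal(den2$huMean, -200)
  expect_equal(den2$huVariance, 10000)
  expect_equal(den2$huEntropy, 1)
  expect_error(densityFeatures(vol, noduleMask(array(FALSE, c(4, 4, 4)))),
               "empty")
})

test_that("large Gaussian sample has near-normal skew and kurtosis", {
  set.seed(17)
  n <- 40^3
  vol <- voxelVolume(array(rnorm(n, -300, 50), c(40, 40, 40)))
  den <- densityFeatures(vol, noduleMask(array(TRUE, c(40, 40, 40))))
  expect_lt(abs(den$huSkew), 3 * sqrt(6 / n))
  expect_lt(abs(den$huKurtosis), 3 * sqrt(24 / n))
})

test_that("entropy grows when two HU populations are mixed", {
  m <- array(TRUE, c(4, 4, 4))
  a <- densityFeatures(voxelVolume(array(-100, c(4, 4, 4))), noduleMask(m))
  b <- densityFeatures(voxelVolume(array(-500, c(4, 4, 4))), noduleMask(m))
  mix <- array(rep(c(-100, -500), each = 32), c(4, 4, 4))
  ab <- densityFeatures(voxelVolume(mix), noduleMask(m))
  expect_gt(ab$huEntropy, a$huEntropy)
  expect_gt(ab$huEntropy, b$huEntropy)
})
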
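test_that("sphere phantom matches analytic volume and is reproducible", {
  spec <- phantomSpec(baseRadius = 10, spacing = c(1, 1, 1))
  ph <- generatePhantom(spec, seed = 3)
  vol <- sum(voxelData(ph@mask)) * prod(spacingMm(ph@mask))
  expect_lt(abs(vol / (4 / 3 * pi * 1000) - 1), 0.02)
  ph2 <- generatePhantom(spec, seed = 3)
  expect_identical(voxelData(ph2@volume), voxelData(ph@volume))
  expect_identical(voxelData(ph2@mask), voxelData(ph@mask))
  expect_equal(ph2@carina, ph@carina)
  # carina is centroid + offset
  ctr <- colMeans(which(voxelData(ph@mask), arr.ind = TRUE) - 1) *
    spacingMm(ph@mask) + originMm(ph@mask)
  expect_equal(ph@carina, as.numeric(ctr + spec@carinaOffset), tolerance = 1e-8)
})

test_that("phantom mask is one 6-connected component with genus-0 surface", {
  for (sc in c(0L, 8L)) {
    ph <- generatePhantom(phantomSpec(baseRadius = 8, spiculeCount = sc,
                                      spiculeLength = 4), seed = 5)
    cleaned <- cleanMask(ph@mask)
    expect_identical(voxelData(cleaned), voxelData(ph@mask))
    mesh <- extractMesh(ph@mask)
    expect_identical(meshEulerCharacteristic(mesh), 2L)
  }
})

test_that("spicules increase surface area monotonically at fixed seed", {
  areas <- vapply(c(0L, 4L, 8L), function(sc) {
    ph <- generatePhantom(phantomSpec(baseRadius = 10, spiculeCount = sc,
                                      spiculeLength = 4), seed = 5)
    sum(vertexAreas(extractMesh(ph@mask)))
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
  # spiculated surface strictly exceeds the volume-equivalent sphere area
  ph <- generatePhantom(phantomSpec(baseRadius = 10, spiculeCount = 8L,
                                    spiculeLength = 4), seed = 5)
  v <- sum(voxelData(ph@mask))
  rEq <- (3 * v / (4 * pi))^(1 / 3)
  expect_gt(sum(vertexAreas(extractMesh(ph@mask))), 4 * pi * rEq^2)
})

test_that("phantom sizing and validation errors are raised", {
  expect_error(phantomSpec(baseRadius = -1), "positive")
  expect_error(generatePhantom(phantomSpec(baseRadius = 10),
                               dimVoxels = c(20, 20, 20)), "sizing")
})

test_that("cohort simulator reproduces configured class marginals", {
  cfg <- cohortSimConfig(nPerClass = c(benign = 10000L, malignant = 10000L),
                         clinical = FALSE)
  tab <- generateFeatureTable(cfg, seed = 3)
  expect_identical(nrow(tab), 20000L)
  pos <- tab$label == "malignant"
  cat57 <- featureCatalog()
  # LLN check at n = 1e4 within 3 SE, including a lognormal marginal
  for (f in c("sila_tex", "hu_mean", "flatness", "volume",
              "estimated_radius")) {
    i <- match(f, cat57$name)
    se <- cat57$cancer_sd[i] / sqrt(10000)
    expect_lt(abs(mean(tab[[f]][pos]) - cat57$cancer_mean[i]), 3 * se)
    seb <- cat57$control_sd[i] / sqrt(10000)
    expect_lt(abs(mean(tab[[f]][!pos]) - cat57$control_mean[i]), 3 * seb)
  }
  # skewed positive features never go negative
  expect_gt(min(tab$volume), 0)
  expect_gt(min(tab$sphere_fit_factor), 1)
})

test_that("no-signal configuration yields null univariate AUCs", {
  cat57 <- featureCatalog()
  idx <- 1:6
  m <- cbind(benign = cat57$cancer_mean[idx], malignant = cat57$cancer_mean[idx])
  s <- cbind(benign = cat57$cancer_sd[idx], malignant = cat57$cancer_sd[idx])
  cfg <- cohortSimConfig(nPerClass = c(benign = 2000L, malignant = 2000L),
                         featureNames = cat57$name[idx], classMeans = m,
                         classSds = s, correlation = "independent",
                         clinical = FALSE)
  tab <- generateFeatureTable(cfg, seed = 8)
  scr <- univariateScreen(tab, features = cat57$name[idx])
  expect_true(all(scr$auc >= 0.45 & scr$auc <= 0.55))
})

test_that("cohort simulator is deterministic and validates inputs", {
  cfg <- cohortSimConfig(nPerClass = c(benign = 5L, malignant = 5L))
  expect_identical(generateFeatureTable(cfg, seed = 4),
                   generateFeatureTable(cfg, seed = 4))
  expect_error(generateFeatureTable(
    cohortSimConfig(nPerClass = c(benign = 0L, malignant = 0L)), seed = 1),
    "empty table")
  bad <- matrix(0.9, 3, 3)
  diag(bad) <- 1
  bad[1, 2] <- bad[2, 1] <- -0.9 # not PSD together with the 0.9s
  expect_error(cohortSimConfig(featureNames = c("a", "b", "c"),
                               classMeans = matrix(0, 3, 2),
                               classSds = matrix(1, 3, 2),
                               correlation = bad,
                               transform = rep("gaussian", 3),
                               shift = rep(0, 3)),
               "semidefinite")
})

test_that("phantom NIfTI output round-trips through the readers", {
  ph <- generatePhantom(phantomSpec(baseRadius = 5,
                                    spacing = c(0.8, 0.8, 1.2)), seed = 6)
  vp <- tempfile(fileext = ".nii.gz")
  mp <- tempfile(fileext = ".nii.gz")
  cp <- tempfile(fileext = ".json")
  writeVolume(ph@volume, vp)
  writeVolume(ph@mask, mp)
  writeCarina(ph@carina, cp)
  v2 <- loadVolume(vp)
  m2 <- loadMask(mp)
  expect_equal(voxelData(v2), voxelData(ph@volume), tolerance = 1e-6)
  # the NIfTI header stores the transform in float32
  expect_equal(spacingMm(v2), spacingMm(ph@volume), tolerance = 1e-6)
  expect_equal(originMm(v2), originMm(ph@volume), tolerance = 1e-6)
  expect_identical(voxelData(m2), voxelData(ph@mask))
  expect_equal(loadCarina(cp), ph@carina)
})
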
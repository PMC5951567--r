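test_that("sphere mesh is closed, consistently oriented, near-analytic", {
  fx <- sphereFixture()
  mesh <- fx$mesh
  expect_identical(meshEulerCharacteristic(mesh), 2L)
  expect_identical(nrow(meshFaces(mesh)), 2L * nrow(meshVertices(mesh)) - 4L)
  expect_lt(abs(meshEnclosedVolume(mesh) / (4 / 3 * pi * 1000) - 1), 0.03)
  expect_lt(abs(sum(vertexAreas(mesh)) / (4 * pi * 100) - 1), 0.03)
  expect_error(extractMesh(noduleMask(array(FALSE, c(4, 4, 4)))), "empty")
  thin <- array(FALSE, c(8, 8, 8))
  thin[3:6, 3:6, 4] <- TRUE
  expect_error(extractMesh(noduleMask(thin)), "degenerate")
})

test_that("smoothing suppresses the voxel staircase", {
  ph <- generatePhantom(phantomSpec(baseRadius = 8), seed = 15)
  raw <- extractMesh(ph@mask, gaussianSigmaMm = 0, taubinIters = 0)
  smooth <- extractMesh(ph@mask)
  cRaw <- principalCurvatures(raw)
  cSm <- principalCurvatures(smooth)
  tot <- function(cf, m) sum(cf@curvedness[cf@reliable] *
                               vertexAreas(m)[cf@reliable])
  expect_lt(tot(cSm, smooth), tot(cRaw, raw))
})

test_that("sphere curvature matches 1/r analytically", {
  fx <- sphereFixture()
  cf <- fx$field
  ok <- cf@reliable
  expect_true(all(cf@kappa1[ok] >= cf@kappa2[ok] - 1e-9))
  expect_lt(abs(median(cf@H[ok]) / 0.1 - 1), 0.05)
  expect_lt(abs(median(cf@K[ok]) / 0.01 - 1), 0.10)
  expect_true(all(cf@shapeIndex[ok] >= -1 & cf@shapeIndex[ok] <= 1))
  expect_true(all(cf@curvedness[ok] >= 0))
  expect_true(all(cf@H[ok]^2 >= cf@K[ok] - 1e-9))
})

test_that("Gauss-Bonnet holds on genus-0 phantoms", {
  fx <- sphereFixture()
  gb <- sum(fx$field@K[fx$field@reliable] *
              vertexAreas(fx$mesh)[fx$field@reliable])
  expect_lt(abs(gb / (4 * pi) - 1), 0.05)
  ph <- generatePhantom(phantomSpec(baseRadius = 7, lobulationAmplitude = 1,
                                    lobulationOrder = 2L), seed = 19)
  mesh <- extractMesh(ph@mask)
  cf <- principalCurvatures(mesh)
  gb2 <- sum(cf@K[cf@reliable] * vertexAreas(mesh)[cf@reliable])
  expect_lt(abs(gb2 / (4 * pi) - 1), 0.05)
})

test_that("capsule tube has cylinder principal curvatures", {
  mask <- capsuleMask(radius = 5, halfLen = 10, spacing = 0.7)
  mesh <- extractMesh(mask)
  cf <- principalCurvatures(mesh)
  onTube <- abs(meshVertices(mesh)[, 3]) < 6 & cf@reliable
  expect_lt(abs(median(cf@kappa1[onTube]) / 0.2 - 1), 0.10)
  expect_lt(abs(median(cf@kappa2[onTube])), 0.02)
})

test_that("curvature summary matches sphere identities", {
  fx <- sphereFixture()
  cs <- curvatureSummary(fx$field, fx$mesh)
  expect_identical(cs$n_vertices, nrow(meshVertices(fx$mesh)))
  expect_identical(cs$n_faces, nrow(meshFaces(fx$mesh)))
  expect_lt(abs(cs$willmore_energy / (4 * pi) - 1), 0.05)
  expect_lt(abs(cs$willmore_energy_2), 0.05 * 4 * pi)
  expect_lt(abs(cs$intrinsic_curv_index - 1), 0.05)
  expect_lt(abs(cs$extrinsic_curv_index / 10 - 1), 0.05)
  expect_lt(cs$avg_sharp, 0.05)        # umbilic everywhere
  expect_lt(abs(cs$avg_curved / 0.1 - 1), 0.05)
  expect_error(principalCurvatures(
    new("SurfaceMesh", vertices = matrix(0, 3, 3),
        faces = matrix(c(1L, 2L, 3L), 1, 3), vertexAreas = rep(0, 3))),
    "too small")
})

test_that("surface exemplars: sphere is peak, plane is flat, torus is mixed", {
  fx <- sphereFixture()
  sed <- surfaceExemplarDistribution(fx$field, fx$mesh)
  expect_gte(unname(proportions(sed)["peak"]), 0.99)
  expect_equal(sum(proportions(sed)), 1, tolerance = 1e-9)
  # synthetic flat field on the same mesh
  n <- length(fx$field@H)
  flat <- new("CurvatureField", kappa1 = rep(0, n), kappa2 = rep(0, n),
              H = rep(0, n), K = rep(0, n), shapeIndex = rep(0, n),
              curvedness = rep(0, n), reliable = rep(TRUE, n))
  sedF <- surfaceExemplarDistribution(flat, fx$mesh)
  expect_equal(unname(proportions(sedF)["flat"]), 1)
  # torus has convex (peak) and saddle regions
  tm <- extractMesh(torusMask())
  tc <- principalCurvatures(tm)
  sedT <- surfaceExemplarDistribution(tc, tm)
  pT <- proportions(sedT)
  expect_gt(pT[["peak"]] + pT[["ridge"]] + pT[["saddle_ridge"]], 0)
  expect_gt(pT[["saddle_ridge"]] + pT[["saddle_valley"]] + pT[["minimal"]], 0.1)
})

test_that("surface SILA metrics behave on degenerate and sphere input", {
  fx <- sphereFixture()
  ssm <- surfaceSilaMetrics(fx$field, fx$mesh)
  expect_gt(ssm$silaMorpheme, 99) # near-degenerate at the aggressive end
  n <- length(fx$field@H)
  allPeak <- new("CurvatureField", kappa1 = rep(0.1, n), kappa2 = rep(0.1, n),
                 H = rep(0.1, n), K = rep(0.01, n), shapeIndex = rep(1, n),
                 curvedness = rep(0.1, n), reliable = rep(TRUE, n))
  s2 <- surfaceSilaMetrics(allPeak, fx$mesh)
  expect_equal(s2$silaMorpheme, 100)
  expect_equal(s2$localSilaAvg, 100)
  expect_equal(s2$localSilaSkew, 0)
  expect_error(surfaceSilaMetrics(fx$field, fx$mesh,
                                  neighborhoodRadiusMm = 0), "radius")
})

test_that("local SILA equals the brute-force neighborhood oracle", {
  ph <- generatePhantom(phantomSpec(baseRadius = 3, spacing = c(1.4, 1.4, 1.4)),
                        seed = 23)
  mesh <- extractMesh(ph@mask)
  expect_lt(nrow(meshVertices(mesh)), 400)
  cf <- principalCurvatures(mesh)
  ssm <- surfaceSilaMetrics(cf, mesh, neighborhoodRadiusMm = 2.5)
  cls <- NoduleRadiomics:::surfaceVertexClasses(cf, 0.02)
  oracle <- oracleLocalSila(meshVertices(mesh), meshFaces(mesh), cls,
                            vertexAreas(mesh), 9, 2.5)
  expect_equal(ssm$localScores, oracle, tolerance = 1e-9)
})

test_that("curvature obeys the scale law and shape index is scale-free", {
  fx <- sphereFixture()
  for (t in c(0.5, 2)) {
    scaled <- new("SurfaceMesh", vertices = meshVertices(fx$mesh) * t,
                  faces = meshFaces(fx$mesh),
                  vertexAreas = vertexAreas(fx$mesh) * t^2)
    cf <- principalCurvatures(scaled)
    ok <- cf@reliable & fx$field@reliable
    expect_equal(median(cf@H[ok]), median(fx$field@H[ok]) / t,
                 tolerance = 0.02)
    expect_equal(median(cf@K[ok]), median(fx$field@K[ok]) / t^2,
                 tolerance = 0.02)
    expect_equal(median(cf@shapeIndex[ok]), median(fx$field@shapeIndex[ok]),
                 tolerance = 0.02)
    cs <- curvatureSummary(cf, scaled)
    cs0 <- curvatureSummary(fx$field, fx$mesh)
    expect_equal(cs$willmore_energy, cs0$willmore_energy, tolerance = 0.02)
  }
})
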
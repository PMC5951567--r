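test_that("region growing recovers the phantom mask", {
  ph <- generatePhantom(phantomSpec(baseRadius = 10), seed = 12)
  d <- dim(voxelData(ph@volume))
  seed <- round(d / 2)
  cube <- rbind(seed - 15L, seed + 15L)
  got <- regionGrowSegment(ph@volume, seed, cube, -400, 200)
  inter <- sum(voxelData(got) & voxelData(ph@mask))
  dice <- 2 * inter / (sum(voxelData(got)) + sum(voxelData(ph@mask)))
  expect_gte(dice, 0.95)
})

test_that("region growing error contracts hold", {
  ph <- generatePhantom(phantomSpec(baseRadius = 10), seed = 12)
  d <- dim(voxelData(ph@volume))
  seed <- round(d / 2)
  cube <- rbind(seed - 15L, seed + 15L)
  # homogeneous volume: the window never separates anything
  flat <- voxelVolume(array(-300, c(21, 21, 21)))
  expect_error(regionGrowSegment(flat, c(11L, 11L, 11L),
                                 rbind(c(3L, 3L, 3L), c(19L, 19L, 19L)),
                                 -400, 200),
               "no boundary")
  expect_error(regionGrowSegment(ph@volume, seed, cube, 100, 200),
               "seed voxel HU")
  expect_error(regionGrowSegment(ph@volume, cube[2, ] + 5L, cube, -400, 200),
               "outside the bounding cube")
})

test_that("segmentation is translation-equivariant", {
  mk <- function(off) {
    a <- array(-800, c(14, 14, 14))
    a[(4:7) + off[1], (4:7) + off[2], (4:7) + off[3]] <- -200
    voxelVolume(a)
  }
  cube <- rbind(c(1L, 1L, 1L), c(14L, 14L, 14L))
  m0 <- regionGrowSegment(mk(c(0, 0, 0)), c(5L, 5L, 5L), cube, -400, 0)
  m1 <- regionGrowSegment(mk(c(3, 2, 1)), c(8L, 7L, 6L), cube, -400, 0)
  idx0 <- which(voxelData(m0), arr.ind = TRUE)
  idx1 <- which(voxelData(m1), arr.ind = TRUE)
  expect_identical(idx1[order(idx1[, 1], idx1[, 2], idx1[, 3]), ] -
                     rep(c(3L, 2L, 1L), each = nrow(idx1)),
                   idx0[order(idx0[, 1], idx0[, 2], idx0[, 3]), ])
})

test_that("mask cleaning removes specks, fills cavities, is idempotent", {
  m <- array(FALSE, c(20, 20, 20))
  m[5:15, 5:15, 5:15] <- TRUE
  m[10, 10, 10] <- FALSE # interior cavity
  m[2, 2, 2] <- TRUE # disconnected speck
  mask <- noduleMask(m)
  out <- cleanMask(mask)
  expect_false(voxelData(out)[2, 2, 2])
  expect_true(voxelData(out)[10, 10, 10])
  expect_identical(sum(voxelData(out)), 1331L)
  expect_identical(voxelData(cleanMask(out)), voxelData(out))
  expect_error(cleanMask(noduleMask(array(FALSE, c(3, 3, 3)))), "empty")
})

test_that("hollow shell is filled to the solid sphere", {
  n <- 31
  cc <- seq_len(n) - 16
  R2 <- outer(outer(cc^2, cc^2, "+"), cc^2, "+")
  solid <- noduleMask(array(R2 <= 100, c(n, n, n)))
  hollow <- noduleMask(array(R2 <= 100 & R2 > 64, c(n, n, n)))
  expect_identical(voxelData(cleanMask(hollow)), voxelData(solid))
})

test_that("surrounding shell has the analytic volume and is disjoint", {
  ph <- generatePhantom(phantomSpec(baseRadius = 10,
                                    spacing = c(0.5, 0.5, 0.5)), seed = 4)
  shell <- surroundShell(ph@mask, distanceMm = 10)
  vol <- sum(voxelData(shell)) * prod(spacingMm(shell))
  expect_lt(abs(vol / (4 / 3 * pi * (20^3 - 10^3)) - 1), 0.03)
  expect_false(any(voxelData(shell) & voxelData(ph@mask)))
  # lung mask equal to the nodule leaves nothing
  empty <- surroundShell(ph@mask, 10, lungMask = ph@mask)
  expect_identical(sum(voxelData(empty)), 0L)
  expect_error(surroundShell(ph@mask, distanceMm = 0), "distanceMm")
})

test_that("distance transform matches the exhaustive oracle", {
  set.seed(91)
  for (rep in 1:3) {
    d <- c(sample(5:12, 1), sample(5:12, 1), sample(5:12, 1))
    m <- array(runif(prod(d)) < 0.1, d)
    if (!any(m)) m[1, 1, 1] <- TRUE
    sp <- runif(3, 0.5, 2.5)
    env <- asNamespace("NoduleRadiomics")
    got <- array(env$.cpp_edt_sq(as.logical(m), d, sp), d)
    expect_equal(got, oracleEdtSq(m, sp), tolerance = 1e-9)
  }
})

test_that("volume loader error contracts hold", {
  expect_error(loadVolume(tempfile()), "no readable images")
  expect_error(loadVolume("x.nii", format = "dicom_series"), "format error")
})
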
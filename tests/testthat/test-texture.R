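test_that("texture exemplar training is deterministic and validates inputs", {
  m1 <- defaultTextureExemplars()
  expect_identical(m1@kind, "texture9")
  expect_identical(m1@ordination, c("V", "R", "O", "I", "Y", "P", "B", "G", "C"))
  expect_identical(nrow(m1@centroids), 9L)
  set.seed(1)
  patches <- replicate(40, array(rnorm(125, sample(c(-900, -500, -100), 1), 30),
                                 c(5, 5, 5)), simplify = FALSE)
  m2 <- fitTextureExemplars(patches, seed = 77)
  m3 <- fitTextureExemplars(patches, seed = 77)
  expect_identical(m2@centroids, m3@centroids)
  expect_error(fitTextureExemplars(patches[1:5]), "at least 9")
  same <- replicate(12, array(0, c(5, 5, 5)), simplify = FALSE)
  expect_error(fitTextureExemplars(same), "distinct")
})

test_that("separable texture families map to distinct exemplars", {
  model <- defaultTextureExemplars()
  means <- c(-950, -800, -650, -500, -350, -200, -50, 100, 250)
  sds <- c(12, 17, 24, 34, 49, 69, 99, 140, 200)
  set.seed(5)
  hit <- character(9)
  for (f in 1:9) {
    vol <- voxelVolume(array(rnorm(20^3, means[f], sds[f]), c(20, 20, 20)))
    mask <- array(FALSE, c(20, 20, 20))
    mask[6:15, 6:15, 6:15] <- TRUE
    d <- classifyNoduleTexture(vol, noduleMask(mask), model)
    expect_gt(max(proportions(d)), 0.9) # degenerate at one exemplar
    expect_equal(sum(proportions(d)), 1, tolerance = 1e-9)
    hit[f] <- names(which.max(proportions(d)))
  }
  expect_identical(length(unique(hit)), 9L) # purity across families
})

test_that("two-texture nodule splits 50/50 across its two exemplars", {
  set.seed(6)
  n <- 26
  a <- array(rnorm(n^3, -950, 12), c(n, n, n))
  a[14:n, , ] <- rnorm(13 * n * n, -650, 24)
  vol <- voxelVolume(a)
  ## two equal-size mask blocks, inset so no descriptor window straddles the
  ## texture interface (voxel labels are then known exactly)
  mask <- array(FALSE, c(n, n, n))
  mask[4:11, 4:23, 4:23] <- TRUE
  mask[16:23, 4:23, 4:23] <- TRUE
  d <- classifyNoduleTexture(vol, noduleMask(mask), defaultTextureExemplars())
  p <- proportions(d)
  expect_lt(abs(p[["V"]] - 0.5), 0.05)
  expect_lt(abs(p[["O"]] - 0.5), 0.05)
})

test_that("texture classification is invariant to grid translation", {
  set.seed(7)
  a <- array(rnorm(18^3, -400, 60), c(18, 18, 18))
  mask <- array(FALSE, c(18, 18, 18))
  mask[5:14, 5:14, 5:14] <- TRUE
  d1 <- classifyNoduleTexture(voxelVolume(a), noduleMask(mask))
  d2 <- classifyNoduleTexture(voxelVolume(a, origin = c(50, -20, 10)),
                              noduleMask(mask, origin = c(50, -20, 10)))
  expect_identical(proportions(d1), proportions(d2))
})

test_that("texture risk maps the ordination onto [1, 3]", {
  mk <- function(p) new("ExemplarDistribution", proportions = p, n = 100,
                        kind = "texture9")
  expect_equal(textureRisk(mk(c(1, rep(0, 8)))), 1)
  expect_equal(textureRisk(mk(c(rep(0, 8), 1))), 3)
  expect_equal(textureRisk(mk(rep(1 / 9, 9))), 2)
  # monotone under any transfer toward the aggressive end
  set.seed(8)
  for (i in 1:10) {
    p <- rgamma(9, 1)
    p <- p / sum(p)
    from <- sample(1:8, 1)
    to <- if (from == 8) 9L else sample((from + 1):9, 1)
    q <- p
    eps <- 0.5 * p[from]
    q[from] <- q[from] - eps
    q[to] <- q[to] + eps
    expect_gt(textureRisk(mk(q)), textureRisk(mk(p)))
  }
})

test_that("parenchymal rules label degenerate shells as expected", {
  n <- 16
  mask <- array(FALSE, c(n, n, n))
  mask[3:14, 3:14, 3:14] <- TRUE
  shell <- noduleMask(mask)
  # uniformly -960 HU: pure severe low attenuation
  p1 <- classifyParenchyma(voxelVolume(array(-960, c(n, n, n))), shell)
  expect_equal(unname(proportions(p1$distribution)["severe_laa"]), 1)
  expect_equal(p1$silaLowAttenuation, 100)
  expect_equal(p1$silaFibrosis, 0)
  # uniformly -800 HU: pure normal lung
  p2 <- classifyParenchyma(voxelVolume(array(-800, c(n, n, n))), shell)
  expect_equal(unname(proportions(p2$distribution)["normal"]), 1)
  expect_equal(p2$silaFibrosis, 0)
  expect_equal(p2$silaLowAttenuation, 0)
})

test_that("every shell voxel receives exactly one label", {
  set.seed(9)
  n <- 14
  hu <- array(runif(n^3, -1100, 300), c(n, n, n))
  mask <- array(runif(n^3) < 0.5, c(n, n, n))
  res <- classifyParenchyma(voxelVolume(hu, clamp = FALSE), noduleMask(mask))
  nShell <- sum(mask)
  nVessel <- res$vesselsPct / 100 * nShell
  nBg <- res$backgroundPct / 100 * nShell
  expect_equal(sum(res$counts) + nVessel + nBg, nShell, tolerance = 1e-9)
  expect_true(all(res$counts >= 0))
})

test_that("empty shell flags parenchymal outputs as missing", {
  res <- suppressWarnings(
    classifyParenchyma(voxelVolume(array(-800, c(4, 4, 4))),
                       noduleMask(array(FALSE, c(4, 4, 4)))))
  expect_true(is.na(res$vesselsPct))
  expect_true(is.na(res$silaFibrosis))
})
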
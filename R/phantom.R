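#' Specify a synthetic nodule phantom
#'
#' A phantom is a star-shaped solid: an ellipsoid whose radius function is
#' modulated by a band-limited angular lobulation, with optional cone-shaped
#' spicules along random directions. Smooth near-spherical specs emulate
#' typical benign nodules; lobulated, spiculated specs emulate the malignant
#' morphology the classifier is meant to detect.
#'
#' @param baseRadius base radius in mm (> 0).
#' @param axisRatios a:b:c semi-axis ratios; the semi-axes are
#'   \code{baseRadius * axisRatios}.
#' @param lobulationAmplitude amplitude (mm) of the angular perturbation.
#' @param lobulationOrder angular frequency of the perturbation (0 = none).
#' @param spiculeCount number of spicules.
#' @param spiculeLength spicule length in mm.
#' @param interiorHuMean,interiorHuSd HU noise inside the nodule.
#' @param backgroundHuMean,backgroundHuSd HU noise of the surrounding lung
#'   (used when \code{shellPattern = "normal"}).
#' @param spacing voxel spacing in mm, numeric(3).
#' @param carinaOffset vector (mm) from the nodule centroid to the simulated
#'   carina landmark.
#' @param shellPattern texture of the surrounding parenchyma: "normal",
#'   "groundglass", "low_attenuation" or "reticular".
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(baseRadius = 8, axisRatios = c(1, 1, 1),
                        lobulationAmplitude = 0, lobulationOrder = 0L,
                        spiculeCount = 0L, spiculeLength = 0,
                        interiorHuMean = -200, interiorHuSd = 30,
                        backgroundHuMean = -800, backgroundHuSd = 30,
                        spacing = c(1, 1, 1), carinaOffset = c(0, 0, -40),
                        shellPattern = "normal") {
  new("PhantomSpec", baseRadius = baseRadius,
      axisRatios = as.numeric(axisRatios),
      lobulationAmplitude = lobulationAmplitude,
      lobulationOrder = as.integer(lobulationOrder),
      spiculeCount = as.integer(spiculeCount),
      spiculeLength = spiculeLength, interiorHuMean = interiorHuMean,
      interiorHuSd = interiorHuSd, backgroundHuMean = backgroundHuMean,
      backgroundHuSd = backgroundHuSd, spacing = as.numeric(spacing),
      carinaOffset = as.numeric(carinaOffset), shellPattern = shellPattern)
}

# background HU distributions per shell pattern (mean, sd); patterns other
# than "normal" use canonical quantitative-CT values
shellPatternParams <- function(spec) {
  switch(spec@shellPattern,
    normal = c(spec@backgroundHuMean, spec@backgroundHuSd),
    groundglass = c(-600, 40),
    low_attenuation = c(-960, 20),
    reticular = c(-450, 130))
}

randomUnitVectors <- function(n) {
  m <- matrix(rnorm(3 * max(n, 1)), ncol = 3)
  m / sqrt(rowSums(m^2))
}

#' Generate a voxel nodule phantom
#'
#' Rasterizes the spec onto a centred grid with at least a 12 mm background
#' margin, fills interior and background with Gaussian HU noise (the
#' background distribution follows \code{shellPattern}), and returns the
#' analytic ground-truth mask and the carina landmark. Identical spec and seed
#' reproduce the phantom bit-for-bit; the geometry and noise random streams
#' are split, so adding spicules to a spec leaves the lobulation and the
#' background noise unchanged.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param seed integer seed.
#' @param dimVoxels optional explicit grid dimensions; an error is raised if
#'   the shape plus margin does not fit.
#' @return a \linkS4class{NodulePhantom}.
#' @export
generatePhantom <- function(spec, seed = 1L, dimVoxels = NULL) {
  validObject(spec)
  marginMm <- 12
  maxR <- spec@baseRadius * max(spec@axisRatios) +
    spec@lobulationAmplitude + spec@spiculeLength
  halfExtent <- maxR + marginMm
  need <- 2L * as.integer(ceiling(halfExtent / spec@spacing)) + 1L
  if (is.null(dimVoxels)) {
    dims <- need
  } else {
    dims <- as.integer(dimVoxels)
    if (any(dims < need))
      stop("sizing error: phantom plus 12 mm margin needs a grid of at least ",
           paste(need, collapse = " x "), " voxels")
  }
  origin <- -(dims - 1) / 2 * spec@spacing

  ## geometry stream: lobulation field, then spicule directions (in order, so
  ## the first k spicules of a (k+1)-spicule spec are identical)
  set.seed(deriveSeed(seed, "geometry"))
  nTerms <- 4L
  lobDirs <- randomUnitVectors(nTerms)
  lobPhase <- runif(nTerms, 0, 2 * pi)
  spicDirs <- if (spec@spiculeCount > 0) randomUnitVectors(spec@spiculeCount)
              else matrix(0, 0, 3)

  cx <- origin[1] + (seq_len(dims[1]) - 1) * spec@spacing[1]
  cy <- origin[2] + (seq_len(dims[2]) - 1) * spec@spacing[2]
  cz <- origin[3] + (seq_len(dims[3]) - 1) * spec@spacing[3]
  X <- array(cx, dims)
  Y <- array(rep(cy, each = dims[1]), dims)
  Z <- array(rep(cz, each = dims[1] * dims[2]), dims)
  R <- sqrt(X^2 + Y^2 + Z^2)
  Rsafe <- pmax(R, 1e-9)
  Ux <- X / Rsafe; Uy <- Y / Rsafe; Uz <- Z / Rsafe

  semi <- spec@baseRadius * spec@axisRatios
  rEll <- 1 / sqrt((Ux / semi[1])^2 + (Uy / semi[2])^2 + (Uz / semi[3])^2)

  rSurf <- rEll
  if (spec@lobulationAmplitude > 0 && spec@lobulationOrder > 0) {
    P <- 0
    for (t in seq_len(nTerms)) {
      ca <- pmin(pmax(Ux * lobDirs[t, 1] + Uy * lobDirs[t, 2] +
                        Uz * lobDirs[t, 3], -1), 1)
      P <- P + cos(spec@lobulationOrder * acos(ca) + lobPhase[t])
    }
    P <- P / max(abs(P))
    rSurf <- rSurf * (1 + spec@lobulationAmplitude / spec@baseRadius * P)
  }
  if (spec@spiculeCount > 0 && spec@spiculeLength > 0) {
    alpha <- 0.3 # spicule half-angle, radians
    for (k in seq_len(spec@spiculeCount)) {
      ca <- pmin(pmax(Ux * spicDirs[k, 1] + Uy * spicDirs[k, 2] +
                        Uz * spicDirs[k, 3], -1), 1)
      psi <- acos(ca)
      rSurf <- rSurf + spec@spiculeLength * pmax(0, 1 - psi / alpha)^2
    }
  }
  maskArr <- R <= rSurf

  ## noise stream: full-volume background first, then interior overwrite
  set.seed(deriveSeed(seed, "noise"))
  bg <- shellPatternParams(spec)
  hu <- array(rnorm(prod(dims), bg[1], bg[2]), dims)
  nIn <- sum(maskArr)
  if (nIn == 0) stop("phantom mask is empty; check the spec")
  hu[maskArr] <- rnorm(nIn, spec@interiorHuMean, spec@interiorHuSd)

  vol <- voxelVolume(hu, spacing = spec@spacing, origin = origin)
  msk <- noduleMask(maskArr, spacing = spec@spacing, origin = origin)
  centroid <- colMeans(maskWorldCoords(msk))
  new("NodulePhantom", volume = vol, mask = msk,
      carina = as.numeric(centroid + spec@carinaOffset), spec = spec,
      seed = as.integer(seed))
}
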
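#' Extract the full 57-feature radiomic panel
#'
#' Runs the complete per-nodule pipeline: location features against the carina
#' landmark, mesh extraction, size/shape/density features, texture exemplar
#' classification and SILA, the 10 mm surrounding-lung shell and its
#' parenchymal classification, per-vertex curvature, surface summary features
#' and surface-exemplar SILA metrics. Values are returned in catalogue order
#' (\code{\link{featureCatalog}}). SILA-family features are reported as
#' 100 x the unit-scale score; \code{centroid_z} is the vertical offset from
#' the carina.
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param mask a \linkS4class{NoduleMask} on the same grid.
#' @param carina numeric(3) carina landmark in world mm.
#' @param textureModel texture exemplar dictionary.
#' @param parenchymaModel parenchymal exemplar dictionary.
#' @param lungMask optional lung mask restricting the shell.
#' @param shellDistanceMm surrounding-shell thickness (mm).
#' @param neighborhoodRadiusMm geodesic radius of local SILA neighborhoods.
#' @param eps curvature flatness tolerance (1/mm).
#' @param gaussianSigmaMm,taubinIters mesh extraction smoothing parameters.
#' @return named numeric(57) in catalogue order.
#' @export
extractFeatures <- function(volume, mask, carina,
                            textureModel = defaultTextureExemplars(),
                            parenchymaModel = defaultParenchymaModel(),
                            lungMask = NULL, shellDistanceMm = 10,
                            neighborhoodRadiusMm = 3, eps = 0.02,
                            gaussianSigmaMm = 1, taubinIters = 10) {
  stopifnotSameGrid(volume, mask)
  loc <- locationFeatures(mask, carina)
  mesh <- extractMesh(mask, gaussianSigmaMm = gaussianSigmaMm,
                      taubinIters = taubinIters)
  shp <- shapeFeatures(mask, mesh)
  den <- densityFeatures(volume, mask)
  texDist <- classifyNoduleTexture(volume, mask, textureModel)
  shell <- surroundShell(mask, distanceMm = shellDistanceMm,
                         lungMask = lungMask)
  par <- classifyParenchyma(volume, shell, parenchymaModel)
  curv <- principalCurvatures(mesh)
  cs <- curvatureSummary(curv, mesh)
  ssm <- surfaceSilaMetrics(curv, mesh,
                            neighborhoodRadiusMm = neighborhoodRadiusMm,
                            eps = eps)
  out <- c(
    centroid_x = loc$centroid[1],
    centroid_y = loc$centroid[2],
    centroid_z = loc$offsetCarinaZ,
    volume = shp$volumeMm3,
    surface_area = shp$surfaceAreaMm2,
    sphericity = shp$sphericity,
    sphere_fit_factor = shp$sphereFitFactor,
    estimated_radius = shp$estimatedRadius,
    min_enclosing_brick_x = shp$brickX,
    min_enclosing_brick_y = shp$brickY,
    min_enclosing_brick = shp$brickZ,
    max_brick_length = shp$maxBrickLength,
    elongation = shp$elongation,
    flatness = shp$flatness,
    hu_mean = den$huMean,
    hu_variance = den$huVariance,
    hu_skew = den$huSkew,
    hu_kurtosis = den$huKurtosis,
    hu_entropy = den$huEntropy,
    location = as.numeric(loc$locationCode),
    sila_tex = 100 * silaScore(texDist),
    texture_risk = textureRisk(texDist),
    vessels = par$vesselsPct,
    background = par$backgroundPct,
    sila_fibrosis = par$silaFibrosis,
    sila_low_attenuation = par$silaLowAttenuation,
    unlist(cs),
    sila_morpheme = ssm$silaMorpheme,
    morpheme_avg_curv = ssm$morphemeAvgCurv,
    morpheme_skew_curv = ssm$morphemeSkewCurv,
    local_sila_avg = ssm$localSilaAvg,
    local_sila_skew = ssm$localSilaSkew)
  out <- out[featureNames57()]
  stopifnot(!anyNA(names(out)))
  out
}

#' Simulate a phantom cohort and extract its feature table
#'
#' Generates smooth near-ellipsoidal phantoms as the benign class and
#' lobulated, spiculated phantoms as the malignant class (radius 3.5-10 mm,
#' i.e. 7-20 mm diameter), extracts the full 57-feature panel from each, and
#' returns a feature table ready for the modeling pipeline.
#'
#' @param nBenign,nMalignant phantoms per class.
#' @param seed integer seed.
#' @param spacing voxel spacing in mm.
#' @return a data.frame with \code{id}, \code{label}, \code{size_mm} and the
#'   57 features.
#' @export
simulatePhantomCohort <- function(nBenign = 20, nMalignant = 20, seed = 1L,
                                  spacing = c(1, 1, 1)) {
  ## class morphologies overlap (benign nodules are allowed mild
  ## irregularity), as in screening cohorts where no single feature separates
  ## the classes
  specOf <- function(cls, r, u) {
    if (cls == "benign") {
      phantomSpec(baseRadius = r,
                  axisRatios = c(1, 1 - 0.15 * u[1], 1 - 0.25 * u[2]),
                  lobulationAmplitude = 0.8 * u[3], lobulationOrder = 2L,
                  spiculeCount = as.integer(2 * u[5]),
                  spiculeLength = 1.5 * u[6],
                  interiorHuMean = -150 - 200 * u[4],
                  carinaOffset = c(0, 0, -(20 + 80 * u[7])),
                  spacing = spacing)
    } else {
      phantomSpec(baseRadius = r,
                  axisRatios = c(1, 1 - 0.3 * u[1], 1 - 0.4 * u[2]),
                  lobulationAmplitude = 0.8 + 1.7 * u[3], lobulationOrder = 3L,
                  spiculeCount = 3L + as.integer(7 * u[5]),
                  spiculeLength = 1.5 + 3.5 * u[6],
                  interiorHuMean = -50 - 150 * u[4],
                  carinaOffset = c(0, 0, -(30 + 80 * u[7])),
                  spacing = spacing)
    }
  }
  rows <- list()
  n <- c(benign = nBenign, malignant = nMalignant)
  for (cls in names(n)) {
    for (i in seq_len(n[[cls]])) {
      s <- deriveSeed(seed, paste0(cls, i))
      set.seed(s)
      r <- runif(1, 3.5, if (cls == "benign") 8 else 10)
      u <- runif(7)
      ph <- generatePhantom(specOf(cls, r, u), seed = s)
      feats <- extractFeatures(ph@volume, ph@mask, ph@carina)
      rows[[length(rows) + 1L]] <-
        data.frame(id = sprintf("P_%s_%03d", cls, i), label = cls,
                   size_mm = 2 * r, t(feats), check.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$label <- factor(out$label, levels = c("benign", "malignant"))
  rownames(out) <- NULL
  out
}
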
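## Central S4 containers. Grids are column-major numeric arrays indexed
## (x, y, z); world coordinates are origin + 0-based index * spacing, in mm.

#' VoxelVolume: a 3D CT grid in Hounsfield units
#'
#' Holds a scalar 3D array of Hounsfield units together with its anisotropic
#' voxel spacing and world origin. Voxel indices are 0-based in world-space
#' arithmetic: the centre of voxel (i, j, k) sits at
#' \code{origin + c(i, j, k) * spacing} mm.
#'
#' @slot values 3D numeric array of HU values.
#' @slot spacing numeric(3), voxel spacing in mm (all > 0).
#' @slot origin numeric(3), world coordinate of voxel (0, 0, 0) in mm.
#' @exportClass VoxelVolume
setClass("VoxelVolume",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(dim(object@values)) != 3L) return("values must be a 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive lengths (mm)")
    if (length(object@origin) != 3L) return("origin must have 3 components")
    TRUE
  })

#' NoduleMask: a binary grid on the lattice of a VoxelVolume
#'
#' @slot values 3D logical array.
#' @slot spacing numeric(3), voxel spacing in mm.
#' @slot origin numeric(3), world origin in mm.
#' @exportClass NoduleMask
setClass("NoduleMask",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(dim(object@values)) != 3L) return("values must be a 3D array")
    if (!is.logical(object@values)) return("mask values must be logical")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive lengths (mm)")
    TRUE
  })

#' PhantomSpec: parameters of a synthetic nodule phantom
#'
#' Describes a star-shaped nodule: an ellipsoid with a band-limited angular
#' lobulation of its radius function and optional cone-shaped spicules, filled
#' with Gaussian HU noise and embedded in simulated lung parenchyma.
#'
#' @slot baseRadius base radius in mm (> 0).
#' @slot axisRatios numeric(3) a:b:c semi-axis ratios (> 0).
#' @slot lobulationAmplitude lobulation amplitude in mm (>= 0).
#' @slot lobulationOrder angular frequency (degree) of the lobulation.
#' @slot spiculeCount number of cone-shaped spicules (>= 0).
#' @slot spiculeLength spicule length in mm (>= 0).
#' @slot interiorHuMean,interiorHuSd HU distribution inside the nodule.
#' @slot backgroundHuMean,backgroundHuSd HU distribution of surrounding lung.
#' @slot spacing numeric(3) voxel spacing in mm.
#' @slot carinaOffset numeric(3) vector from nodule centroid to the carina
#'   landmark, in mm.
#' @slot shellPattern surrounding-parenchyma pattern: one of
#'   \code{"normal"}, \code{"groundglass"}, \code{"low_attenuation"},
#'   \code{"reticular"}.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(baseRadius = "numeric", axisRatios = "numeric",
    lobulationAmplitude = "numeric", lobulationOrder = "integer",
    spiculeCount = "integer", spiculeLength = "numeric",
    interiorHuMean = "numeric", interiorHuSd = "numeric",
    backgroundHuMean = "numeric", backgroundHuSd = "numeric",
    spacing = "numeric", carinaOffset = "numeric", shellPattern = "character"),
  validity = function(object) {
    if (object@baseRadius <= 0) return("baseRadius must be positive")
    if (length(object@axisRatios) != 3L || any(object@axisRatios <= 0))
      return("axisRatios must be 3 positive scalars")
    if (object@lobulationAmplitude < 0) return("lobulationAmplitude must be >= 0")
    if (object@lobulationOrder < 0) return("lobulationOrder must be >= 0")
    if (object@spiculeCount < 0) return("spiculeCount must be >= 0")
    if (object@spiculeLength < 0) return("spiculeLength must be >= 0")
    if (object@interiorHuSd < 0 || object@backgroundHuSd < 0)
      return("HU standard deviations must be >= 0")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing components must be positive")
    if (length(object@carinaOffset) != 3L)
      return("carinaOffset must have 3 components")
    if (!object@shellPattern %in%
        c("normal", "groundglass", "low_attenuation", "reticular"))
      return("unknown shellPattern")
    TRUE
  })

#' NodulePhantom: a generated phantom with its ground truth
#'
#' @slot volume a \linkS4class{VoxelVolume}.
#' @slot mask a \linkS4class{NoduleMask} (the analytic ground-truth mask).
#' @slot carina numeric(3) world coordinate of the carina landmark (mm).
#' @slot spec the generating \linkS4class{PhantomSpec}.
#' @slot seed integer seed used.
#' @exportClass NodulePhantom
setClass("NodulePhantom",
  representation(volume = "VoxelVolume", mask = "NoduleMask",
    carina = "numeric", spec = "PhantomSpec", seed = "integer"))

#' SurfaceMesh: a closed triangulated nodule surface
#'
#' @slot vertices n x 3 matrix of world-mm coordinates.
#' @slot faces m x 3 integer matrix (1-based), consistently oriented outward.
#' @slot vertexAreas numeric(n) barycentric one-third triangle area weights.
#' @exportClass SurfaceMesh
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix",
    vertexAreas = "numeric"),
  validity = function(object) {
    if (ncol(object@vertices) != 3L) return("vertices must be n x 3")
    if (ncol(object@faces) != 3L) return("faces must be m x 3")
    if (nrow(object@vertices) != length(object@vertexAreas))
      return("vertexAreas must match vertex count")
    f <- object@faces
    if (nrow(f) > 0 && (min(f) < 1 || max(f) > nrow(object@vertices)))
      return("face indices out of range")
    TRUE
  })

#' CurvatureField: per-vertex principal curvatures and derived quantities
#'
#' Quantities follow the outward-normal convention: a convex sphere has
#' kappa1 = kappa2 = 1/r > 0. Shape index is
#' (2/pi) * atan((kappa1 + kappa2) / (kappa1 - kappa2)) with umbilic points
#' assigned +/-1 by the sign of the mean curvature and flat points 0;
#' curvedness is sqrt((kappa1^2 + kappa2^2) / 2).
#'
#' @slot kappa1,kappa2 principal curvatures in 1/mm, kappa1 >= kappa2.
#' @slot H mean curvature (kappa1 + kappa2) / 2.
#' @slot K Gaussian curvature kappa1 * kappa2.
#' @slot shapeIndex Koenderink shape index in [-1, 1].
#' @slot curvedness Koenderink curvedness (>= 0).
#' @slot reliable logical flag per vertex (FALSE where the local quadric fit
#'   was ill-conditioned).
#' @exportClass CurvatureField
setClass("CurvatureField",
  representation(kappa1 = "numeric", kappa2 = "numeric", H = "numeric",
    K = "numeric", shapeIndex = "numeric", curvedness = "numeric",
    reliable = "logical"),
  validity = function(object) {
    n <- length(object@kappa1)
    if (any(vapply(list(object@kappa2, object@H, object@K, object@shapeIndex,
                        object@curvedness), length, 1L) != n) ||
        length(object@reliable) != n)
      return("all curvature slots must have equal length")
    ok <- object@reliable
    if (any(object@kappa1[ok] < object@kappa2[ok] - 1e-9))
      return("kappa1 must be >= kappa2")
    TRUE
  })

#' ExemplarModel: a texture, surface or parenchymal exemplar dictionary
#'
#' An ordinated set of prototype classes to which voxels or mesh vertices are
#' assigned. Texture models (kind \code{"texture9"}) carry k-means centroids
#' over patch descriptors; parenchymal models (kind \code{"parenchyma7"})
#' carry HU threshold rules; surface models (kind \code{"surface9"}) are
#' purely rule-based on curvature signs.
#'
#' @slot kind one of \code{"texture9"}, \code{"surface9"},
#'   \code{"parenchyma7"}.
#' @slot exemplarLabels character labels of the exemplars.
#' @slot ordination permutation of \code{exemplarLabels}, ordered from most
#'   indolent to most aggressive.
#' @slot centroids numeric matrix (one row per exemplar) of standardized patch
#'   descriptors, or a 0 x 0 matrix when not applicable.
#' @slot descriptorCenter,descriptorScale standardization of descriptors
#'   (texture models).
#' @slot thresholds named list of HU rules (parenchymal models).
#' @exportClass ExemplarModel
setClass("ExemplarModel",
  representation(kind = "character", exemplarLabels = "character",
    ordination = "character", centroids = "matrix",
    descriptorCenter = "numeric", descriptorScale = "numeric",
    thresholds = "list"),
  validity = function(object) {
    if (!object@kind %in% c("texture9", "surface9", "parenchyma7"))
      return("unknown model kind")
    if (!setequal(object@ordination, object@exemplarLabels) ||
        length(object@ordination) != length(object@exemplarLabels))
      return("ordination must be a permutation of exemplarLabels")
    if (object@kind == "texture9" && nrow(object@centroids) != 9L)
      return("texture9 model must have exactly 9 centroids")
    TRUE
  })

#' ExemplarDistribution: proportions over an ordinated exemplar set
#'
#' @slot proportions named non-negative numeric over the ordination (most
#'   indolent first); sums to 1 when \code{n > 0}.
#' @slot n number of voxels or vertices (or total area weight) classified.
#' @slot kind the exemplar-model kind the distribution refers to.
#' @exportClass ExemplarDistribution
setClass("ExemplarDistribution",
  representation(proportions = "numeric", n = "numeric", kind = "character"),
  validity = function(object) {
    if (any(object@proportions < -1e-12)) return("proportions must be >= 0")
    if (object@n > 0 && abs(sum(object@proportions) - 1) > 1e-9)
      return("proportions must sum to 1")
    TRUE
  })

#' CohortSimConfig: configuration of the cohort feature-table simulator
#'
#' Per-class marginal means and standard deviations for the 57-feature panel
#' (defaults are the published cancer/control cohort marginals), a correlation
#' structure imposed through a Gaussian copula, and the per-feature marginal
#' family (Gaussian, or shifted lognormal for skewed positive features).
#'
#' @slot nPerClass named integer(2): rows per class, names "benign" and
#'   "malignant".
#' @slot featureNames ordered character(57) of feature identifiers.
#' @slot classMeans,classSds 57 x 2 numeric matrices (columns benign,
#'   malignant).
#' @slot correlation 57 x 57 correlation matrix (symmetric PSD, unit
#'   diagonal).
#' @slot transform character(57): "gaussian" or "lognormal" per feature.
#' @slot shift numeric(57): lower shift of the lognormal marginals.
#' @slot clinical logical: attach simulated clinical covariates (age,
#'   pack-years, sex) drawn from the published demographics.
#' @exportClass CohortSimConfig
setClass("CohortSimConfig",
  representation(nPerClass = "integer", featureNames = "character",
    classMeans = "matrix", classSds = "matrix", correlation = "matrix",
    transform = "character", shift = "numeric", clinical = "logical"),
  validity = function(object) {
    p <- length(object@featureNames)
    if (length(object@nPerClass) != 2L || any(object@nPerClass < 0))
      return("nPerClass must be two non-negative counts")
    if (!identical(dim(object@classMeans), c(p, 2L)) ||
        !identical(dim(object@classSds), c(p, 2L)))
      return("classMeans/classSds must be p x 2")
    if (any(object@classSds < 0)) return("SDs must be >= 0")
    if (!identical(dim(object@correlation), c(p, p)))
      return("correlation must be p x p")
    if (max(abs(object@correlation - t(object@correlation))) > 1e-8)
      return("correlation must be symmetric")
    if (max(abs(diag(object@correlation) - 1)) > 1e-8)
      return("correlation must have unit diagonal")
    ev <- eigen(object@correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) return("correlation must be positive semidefinite")
    if (!all(object@transform %in% c("gaussian", "lognormal")))
      return("transform must be gaussian or lognormal")
    TRUE
  })

#' StabilitySelectionResult: per-feature LASSO selection frequencies
#'
#' @slot frequencies named numeric in [0, 1]: fraction of runs in which each
#'   feature had a non-zero coefficient at the CV-chosen penalty.
#' @slot selected character: features with frequency >= threshold.
#' @slot runs,threshold,seed the run parameters.
#' @exportClass StabilitySelectionResult
setClass("StabilitySelectionResult",
  representation(frequencies = "numeric", selected = "character",
    runs = "integer", threshold = "numeric", seed = "integer"),
  validity = function(object) {
    if (any(object@frequencies < 0 | object@frequencies > 1))
      return("frequencies must be in [0, 1]")
    if (!all(object@selected %in% names(object@frequencies)))
      return("selected must be a subset of the screened features")
    TRUE
  })

#' FittedClassifier: a standardized logistic model on selected features
#'
#' @slot features character: model features (order matches coefficients).
#' @slot coefficients named numeric: intercept + per-feature coefficients on
#'   the standardized scale.
#' @slot center,scale standardization parameters per feature.
#' @slot pValues per-coefficient Wald p-values.
#' @exportClass FittedClassifier
setClass("FittedClassifier",
  representation(features = "character", coefficients = "numeric",
    center = "numeric", scale = "numeric", pValues = "numeric"),
  validity = function(object) {
    if (length(object@coefficients) != length(object@features) + 1L)
      return("coefficients must be intercept + one per feature")
    if (any(!is.finite(object@coefficients)))
      return("coefficients must be finite")
    TRUE
  })

#' ValidationReport: optimism-corrected bootstrap validation summary
#'
#' @slot apparentAuc AUC of the procedure's model on the training data.
#' @slot optimism mean bootstrap optimism.
#' @slot correctedAuc apparentAuc - optimism (exact identity).
#' @slot youdenCutoff,sensitivity,specificity Youden-index operating point of
#'   the apparent model.
#' @slot B number of bootstrap resamples.
#' @slot n number of rows validated.
#' @slot ablation data.frame of leave-one-feature-out rows (may be empty).
#' @slot details list of diagnostics (per-resample optimism, failures, seed).
#' @exportClass ValidationReport
setClass("ValidationReport",
  representation(apparentAuc = "numeric", optimism = "numeric",
    correctedAuc = "numeric", youdenCutoff = "numeric",
    sensitivity = "numeric", specificity = "numeric", B = "integer",
    n = "integer", ablation = "data.frame", details = "list"),
  validity = function(object) {
    if (abs(object@correctedAuc - (object@apparentAuc - object@optimism)) >
        1e-12)
      return("correctedAuc must equal apparentAuc - optimism")
    if (object@sensitivity < 0 || object@sensitivity > 1 ||
        object@specificity < 0 || object@specificity > 1)
      return("sensitivity/specificity must be in [0, 1]")
    TRUE
  })
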
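#' Accessors for NoduleRadiomics objects
#'
#' Slot accessors for the grid, mesh, exemplar and model containers.
#'
#' @param x an object of the corresponding class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("voxelData", "VoxelVolume", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("voxelData", "NoduleMask", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("spacingMm", "VoxelVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("spacingMm", "NoduleMask", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("originMm", "VoxelVolume", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("originMm", "NoduleMask", function(x) x@origin)

#' @rdname accessors
#' @export
setMethod("meshVertices", "SurfaceMesh", function(x) x@vertices)
#' @rdname accessors
#' @export
setMethod("meshFaces", "SurfaceMesh", function(x) x@faces)
#' @rdname accessors
#' @export
setMethod("vertexAreas", "SurfaceMesh", function(x) x@vertexAreas)

#' @rdname accessors
#' @export
setMethod("proportions", "ExemplarDistribution", function(x) x@proportions)
#' @rdname accessors
#' @export
setMethod("ordination", "ExemplarModel", function(x) x@ordination)
#' @rdname accessors
#' @export
setMethod("exemplarLabels", "ExemplarModel", function(x) x@exemplarLabels)

#' @rdname accessors
#' @export
setMethod("selectionFrequencies", "StabilitySelectionResult",
          function(x) x@frequencies)
#' @rdname accessors
#' @export
setMethod("selectedFeatures", "StabilitySelectionResult",
          function(x) x@selected)
#' @rdname accessors
#' @export
setMethod("selectedFeatures", "FittedClassifier", function(x) x@features)

#' @rdname accessors
#' @export
setMethod("apparentAuc", "ValidationReport", function(x) x@apparentAuc)
#' @rdname accessors
#' @export
setMethod("correctedAuc", "ValidationReport", function(x) x@correctedAuc)
#' @rdname accessors
#' @export
setMethod("optimism", "ValidationReport", function(x) x@optimism)

#' @export
setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("VoxelVolume %d x %d x %d, spacing %s mm, HU range [%g, %g]\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = " x "),
              min(object@values), max(object@values)))
})

#' @export
setMethod("show", "NoduleMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("NoduleMask %d x %d x %d, spacing %s mm, %d voxels set\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = " x "),
              sum(object@values)))
})

#' @export
setMethod("show", "NodulePhantom", function(object) {
  cat(sprintf(
    "NodulePhantom: base radius %g mm, %d spicules, seed %d\n",
    object@spec@baseRadius, object@spec@spiculeCount, object@seed))
  show(object@volume)
  show(object@mask)
})

#' @export
setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces, area %.1f mm^2\n",
              nrow(object@vertices), nrow(object@faces),
              sum(object@vertexAreas)))
})

#' @export
setMethod("show", "CurvatureField", function(object) {
  ok <- object@reliable
  cat(sprintf(
    "CurvatureField: %d vertices (%d reliable), median H %.4g 1/mm, median K %.4g 1/mm^2\n",
    length(ok), sum(ok), stats::median(object@H[ok]),
    stats::median(object@K[ok])))
})

#' @export
setMethod("show", "ExemplarModel", function(object) {
  cat(sprintf("ExemplarModel '%s': %d exemplars\n  ordination: %s\n",
              object@kind, length(object@exemplarLabels),
              paste(object@ordination, collapse = " < ")))
})

#' @export
setMethod("show", "ExemplarDistribution", function(object) {
  cat(sprintf("ExemplarDistribution (%s), n = %g\n", object@kind, object@n))
  print(round(object@proportions, 4))
})

#' @export
setMethod("show", "StabilitySelectionResult", function(object) {
  cat(sprintf(
    "StabilitySelectionResult: %d runs, threshold %.2f, %d features selected\n",
    object@runs, object@threshold, length(object@selected)))
  if (length(object@selected))
    cat("  ", paste(object@selected, collapse = ", "), "\n")
})

#' @export
setMethod("show", "FittedClassifier", function(object) {
  cat(sprintf("FittedClassifier: %d features (standardized logistic)\n",
              length(object@features)))
  print(round(object@coefficients, 4))
})

#' @export
setMethod("show", "ValidationReport", function(object) {
  cat(sprintf(
    paste0("ValidationReport (B = %d, n = %d)\n",
           "  apparent AUC  %.4f\n  optimism      %.4f\n",
           "  corrected AUC %.4f\n",
           "  Youden cutoff %.3f (sens %.3f, spec %.3f)\n"),
    object@B, object@n, object@apparentAuc, object@optimism,
    object@correctedAuc, object@youdenCutoff, object@sensitivity,
    object@specificity))
  if (nrow(object@ablation)) {
    cat("  ablation rows:", nrow(object@ablation), "\n")
  }
})
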
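#' Location features
#'
#' Centroid of the mask in world mm, vertical offset from the carina landmark
#' (centroid_z - carina_z), and an ordinal 6-region location code from a fixed
#' geometric partition (left/right halves x upper/middle/lower thirds) of the
#' lung bounding box (the volume extent when no lung mask is available).
#'
#' @param mask a \linkS4class{NoduleMask}.
#' @param carina numeric(3) world coordinate of the carina (mm).
#' @param lungBox optional 2 x 3 matrix (rows: lower/upper world corners, mm)
#'   of the lung bounding box; defaults to the mask grid extent.
#' @return list with \code{centroid} (numeric(3)), \code{offsetCarinaZ} and
#'   \code{locationCode} (1-6).
#' @export
locationFeatures <- function(mask, carina, lungBox = NULL) {
  if (!any(mask@values)) stop("validation error: empty mask")
  cw <- colMeans(maskWorldCoords(mask))
  if (is.null(lungBox)) {
    d <- dim(mask@values)
    lungBox <- rbind(mask@origin, mask@origin + (d - 1) * mask@spacing)
  }
  fx <- (cw[1] - lungBox[1, 1]) / max(lungBox[2, 1] - lungBox[1, 1], 1e-9)
  fz <- (cw[3] - lungBox[1, 3]) / max(lungBox[2, 3] - lungBox[1, 3], 1e-9)
  side <- if (fx < 0.5) 0L else 3L
  third <- min(2L, max(0L, as.integer(fz * 3)))
  list(centroid = as.numeric(cw),
       offsetCarinaZ = as.numeric(cw[3] - carina[3]),
       locationCode = side + third + 1L)
}

#' Size features: volume and surface area
#'
#' Volume is voxel count times voxel volume; surface area is the total area of
#' the extracted triangulated surface (a mesh can be passed in to avoid
#' re-extraction).
#'
#' @param mask a \linkS4class{NoduleMask}.
#' @param mesh optional \linkS4class{SurfaceMesh} of the mask.
#' @return list with \code{volumeMm3} and \code{surfaceAreaMm2}.
#' @export
sizeFeatures <- function(mask, mesh = NULL) {
  if (!any(mask@values)) stop("validation error: empty mask")
  vol <- sum(mask@values) * prod(mask@spacing)
  if (is.null(mesh))
    mesh <- tryCatch(extractMesh(mask), error = function(e) NULL)
  area <- if (is.null(mesh)) NA_real_ else sum(mesh@vertexAreas)
  list(volumeMm3 = vol, surfaceAreaMm2 = area)
}

#' Bulk shape features
#'
#' Sphericity pi^(1/3) (6V)^(2/3) / A, sphere fit factor A^3 / (36 pi V^2)
#' (the reciprocal cube of sphericity; 1 for a sphere), volume-equivalent
#' radius, and the PCA-oriented bounding brick: extents of the voxel world
#' coordinates projected on the principal axes, sorted descending
#' (brick_x >= brick_y >= brick_z), with elongation = ln(brick_y / brick_x)
#' and flatness = ln(brick_z / brick_x) (both <= 0).
#'
#' @param mask a \linkS4class{NoduleMask}.
#' @param mesh optional \linkS4class{SurfaceMesh} for the surface area.
#' @param flatnessFloor value replacing ln(0) for degenerate (coplanar) masks.
#' @return named list of shape features.
#' @export
shapeFeatures <- function(mask, mesh = NULL, flatnessFloor = -10) {
  if (!any(mask@values)) stop("validation error: empty mask")
  if (is.null(mesh)) mesh <- extractMesh(mask)
  sz <- sizeFeatures(mask, mesh)
  V <- sz$volumeMm3
  A <- sz$surfaceAreaMm2
  ## sphericity-type ratios use the mesh-enclosed volume so that the
  ## isoperimetric inequality bounds them at exactly 1 for a sphere
  Vm <- meshEnclosedVolume(mesh)
  w <- maskWorldCoords(mask)
  extents <- if (nrow(w) >= 4) {
    pc <- prcomp(w, center = TRUE, scale. = FALSE)
    proj <- pc$x
    apply(proj, 2, function(p) diff(range(p))) + mean(mask@spacing)
  } else {
    diff(apply(w, 2, range)) + mask@spacing
  }
  extents <- sort(as.numeric(extents), decreasing = TRUE)
  logRatio <- function(num, den)
    if (num <= 0) flatnessFloor else log(num / den)
  list(volumeMm3 = V, surfaceAreaMm2 = A,
       sphericity = pi^(1 / 3) * (6 * Vm)^(2 / 3) / A,
       sphereFitFactor = A^3 / (36 * pi * Vm^2),
       estimatedRadius = (3 * V / (4 * pi))^(1 / 3),
       brickX = extents[1], brickY = extents[2], brickZ = extents[3],
       maxBrickLength = extents[1],
       elongation = logRatio(extents[2], extents[1]),
       flatness = logRatio(extents[3], extents[1]))
}

#' Radiodensity features
#'
#' Population moments of the masked HU values: mean, variance, standardized
#' skewness, excess kurtosis, and the Shannon entropy (bits) of the masked-HU
#' histogram over fixed bins spanning [-1024, 3071].
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param mask a \linkS4class{NoduleMask} on the same grid.
#' @param binWidthHu histogram bin width in HU (default 1).
#' @return named list with \code{huMean}, \code{huVariance}, \code{huSkew},
#'   \code{huKurtosis} (excess), \code{huEntropy}.
#' @export
densityFeatures <- function(volume, mask, binWidthHu = 1) {
  stopifnotSameGrid(volume, mask)
  x <- volume@values[mask@values]
  if (length(x) == 0) stop("validation error: empty mask")
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v <= 0) {
    return(list(huMean = m, huVariance = 0, huSkew = 0, huKurtosis = 0,
                huEntropy = 0))
  }
  bins <- floor((pmin(pmax(x, -1024), 3071) + 1024) / binWidthHu)
  p <- tabulate(bins + 1L)
  p <- p[p > 0] / length(x)
  list(huMean = m, huVariance = v, huSkew = popSkew(x),
       huKurtosis = popExcessKurtosis(x), huEntropy = -sum(p * log2(p)))
}
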
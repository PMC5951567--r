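## Internal helpers: seed splitting, moment statistics, grid constructors.

# Deterministically derive a sub-seed below 2^31 from a base seed and a
# component key (string or integer). Counter-based splitting keeps the
# geometry, noise and resampling streams independent under partial re-runs.
deriveSeed <- function(seed, key) {
  if (is.character(key)) key <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  h <- (as.double(seed) * 2654435761 + as.double(key) * 40503 + 97) %%
    2147483647
  as.integer(h)
}

# population moments; skewness and excess kurtosis are the standardized
# 3rd/4th central moments, defined as 0 for zero-variance input
popSkew <- function(x, w = NULL) {
  if (length(x) == 0) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(x))
  w <- w / sum(w)
  m <- sum(w * x)
  v <- sum(w * (x - m)^2)
  # zero variance (up to floating-point noise) has skew 0 by convention
  if (v <= (1e-10 * (1 + abs(m)))^2) return(0)
  sum(w * (x - m)^3) / v^1.5
}

popExcessKurtosis <- function(x, w = NULL) {
  if (length(x) == 0) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(x))
  w <- w / sum(w)
  m <- sum(w * x)
  v <- sum(w * (x - m)^2)
  if (v <= 0) return(0)
  sum(w * (x - m)^4) / v^2 - 3
}

# round-half-up at d decimals (base round() is round-half-even)
roundHalfUp <- function(x, d = 1) floor(x * 10^d + 0.5) / 10^d

#' Construct a VoxelVolume
#'
#' @param values 3D numeric array of HU values.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) world coordinate of voxel (0, 0, 0) in mm.
#' @param clamp clamp values into the valid HU range [-1024, 3071].
#' @return a \linkS4class{VoxelVolume}.
#' @export
voxelVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        clamp = TRUE) {
  if (clamp) values[] <- pmin(pmax(values, -1024), 3071)
  new("VoxelVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a NoduleMask
#'
#' @param values 3D logical (or coercible) array.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) world origin in mm.
#' @return a \linkS4class{NoduleMask}.
#' @export
noduleMask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- array(as.logical(values), dim = dim(values))
  new("NoduleMask", values = v, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

# world coordinates (n x 3 matrix, mm) of the TRUE voxels of a mask
maskWorldCoords <- function(mask) {
  idx <- which(mask@values, arr.ind = TRUE) - 1
  sweep(sweep(idx, 2, mask@spacing, "*"), 2, mask@origin, "+")
}

stopifnotSameGrid <- function(volume, mask) {
  if (!identical(dim(volume@values), dim(mask@values)))
    stop("volume and mask must share the same grid dimensions")
  invisible(TRUE)
}

exemplarDistribution <- function(proportions, n, kind) {
  new("ExemplarDistribution", proportions = proportions, n = as.numeric(n),
      kind = kind)
}
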
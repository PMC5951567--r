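## separable Gaussian smoothing of a 3D array (kernel truncated at 3 sigma)
convolveAxis <- function(arr, k, ax) {
  d <- dim(arr)
  n <- d[ax]
  r <- (length(k) - 1) / 2
  K <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- seq_len(n)
    j <- idx + o
    ok <- j >= 1 & j <= n
    K[cbind(idx[ok], j[ok])] <- k[o + r + 1]
  }
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  da <- dim(a)
  a <- array(K %*% matrix(a, nrow = n), da)
  aperm(a, order(perm))
}

gaussSmooth3 <- function(arr, sigmaVox) {
  for (ax in 1:3) {
    s <- sigmaVox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    arr <- convolveAxis(arr, k / sum(k), ax)
  }
  arr
}

#' Extract a triangulated nodule surface
#'
#' The binary mask is Gaussian-smoothed (sigma in mm, per-axis kernels on the
#' anisotropic grid) and the 0.5 level set is triangulated by marching
#' tetrahedra, which yields a closed, consistently outward-oriented surface.
#' Taubin lambda/mu smoothing then suppresses the residual voxel staircase
#' without shrinking the surface. Vertices are in world mm.
#'
#' @param mask a \linkS4class{NoduleMask}.
#' @param gaussianSigmaMm pre-smoothing bandwidth in mm (0 disables).
#' @param taubinIters Taubin smoothing iterations (0 disables).
#' @param taubinLambda,taubinMu Taubin step sizes (defaults 0.5 / -0.53).
#' @return a \linkS4class{SurfaceMesh}.
#' @export
extractMesh <- function(mask, gaussianSigmaMm = 1, taubinIters = 10,
                        taubinLambda = 0.5, taubinMu = -0.53) {
  if (!any(mask@values)) stop("validation error: empty mask")
  idx <- which(mask@values, arr.ind = TRUE)
  bb <- apply(idx, 2, range)
  if (any(bb[2, ] - bb[1, ] < 1))
    stop("degenerate surface: mask thinner than 2 voxels along an axis")
  sigmaVox <- gaussianSigmaMm / mask@spacing
  pad <- pmax(2L, as.integer(ceiling(3 * sigmaVox)) + 2L)
  d <- dim(mask@values)
  lo <- pmax(bb[1, ] - pad, 1L)
  hi <- pmin(bb[2, ] + pad, d)
  sub <- mask@values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  ds <- dim(sub)
  ## zero padding so the level set closes even at the crop boundary
  field <- array(0, ds + 2L)
  field[2:(ds[1] + 1), 2:(ds[2] + 1), 2:(ds[3] + 1)] <- as.numeric(sub)
  iso <- 0.5
  if (gaussianSigmaMm > 0) {
    field <- gaussSmooth3(field, sigmaVox)
    ## Gaussian smoothing drags the 0.5 level set of a convex body inward by
    ## ~ sigma^2 H; compensate with a global iso shift phi(0) * sigma * H0,
    ## where H0 = 1 / volume-equivalent radius, keeping the field smooth
    rEff <- (3 * sum(mask@values) * prod(mask@spacing) / (4 * pi))^(1 / 3)
    iso <- max(0.3, 0.5 - 0.3989 * gaussianSigmaMm / rEff)
  }
  field[abs(field - iso) < 1e-12] <- iso + 1e-9
  origin <- mask@origin + (lo - 2) * mask@spacing
  mt <- .cpp_marching_tet(as.numeric(field), dim(field), mask@spacing,
                          origin, iso)
  V <- mt$vertices
  F <- mt$faces
  if (nrow(V) < 4 || nrow(F) < 4)
    stop("degenerate surface: level set produced no closed surface")
  if (taubinIters > 0)
    V <- .cpp_taubin_smooth(V, F, taubinLambda, taubinMu,
                            as.integer(taubinIters))
  ## enforce globally outward orientation (positive enclosed volume)
  if (meshSignedVolume(V, F) < 0) F <- F[, c(1, 3, 2)]
  new("SurfaceMesh", vertices = V, faces = F,
      vertexAreas = as.numeric(.cpp_vertex_areas(V, F)))
}

meshSignedVolume <- function(V, F) {
  v0 <- V[F[, 1], , drop = FALSE]
  v1 <- V[F[, 2], , drop = FALSE]
  v2 <- V[F[, 3], , drop = FALSE]
  sum(v0[, 1] * (v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2]) -
      v0[, 2] * (v1[, 1] * v2[, 3] - v1[, 3] * v2[, 1]) +
      v0[, 3] * (v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])) / 6
}

#' Mesh summary quantities
#'
#' Enclosed volume (divergence theorem; positive for outward orientation) and
#' the Euler characteristic V - E + F (2 for a closed genus-0 surface).
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return a numeric scalar.
#' @export
meshEnclosedVolume <- function(mesh) {
  meshSignedVolume(mesh@vertices, mesh@faces)
}

#' @rdname meshEnclosedVolume
#' @export
meshEulerCharacteristic <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  nrow(mesh@vertices) - nrow(e) + nrow(f)
}
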
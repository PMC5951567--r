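#' Seeded region-growing segmentation
#'
#' Grows a 6-connected region from a seed voxel over all voxels whose HU lies
#' in [huLow, huHigh], clipped to an operator-specified bounding cube. A
#' simplification of texture-based parametric region growing: the HU-window
#' flood suffices for phantom data and keeps the operator contract (bounding
#' cube + seed) intact.
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param seedPoint integer(3) voxel index (1-based) inside the nodule.
#' @param boundingCube 2 x 3 integer matrix: first row the lower, second row
#'   the upper 1-based voxel corner (inclusive).
#' @param huLow,huHigh HU window of the grown region.
#' @return a \linkS4class{NoduleMask}.
#' @export
regionGrowSegment <- function(volume, seedPoint, boundingCube,
                              huLow, huHigh) {
  d <- dim(volume@values)
  seedPoint <- as.integer(seedPoint)
  lo <- as.integer(boundingCube[1, ])
  hi <- as.integer(boundingCube[2, ])
  if (any(lo < 1) || any(hi > d) || any(lo > hi))
    stop("bounding cube out of volume bounds")
  if (any(seedPoint < lo) || any(seedPoint > hi))
    stop("validation error: seed point outside the bounding cube")
  hu0 <- volume@values[seedPoint[1], seedPoint[2], seedPoint[3]]
  if (hu0 < huLow || hu0 > huHigh)
    stop("validation error: seed voxel HU (", hu0,
         ") outside the window [", huLow, ", ", huHigh, "]")
  grown <- .cpp_flood_fill6(as.numeric(volume@values), d, seedPoint - 1L,
                            lo - 1L, hi - 1L, huLow, huHigh)
  m <- array(grown, d)
  ## if the grown region reaches half or more of the cube faces the window
  ## failed to separate nodule from background
  touches <- c(any(m[lo[1], lo[2]:hi[2], lo[3]:hi[3]]),
               any(m[hi[1], lo[2]:hi[2], lo[3]:hi[3]]),
               any(m[lo[1]:hi[1], lo[2], lo[3]:hi[3]]),
               any(m[lo[1]:hi[1], hi[2], lo[3]:hi[3]]),
               any(m[lo[1]:hi[1], lo[2]:hi[2], lo[3]]),
               any(m[lo[1]:hi[1], lo[2]:hi[2], hi[3]]))
  if (sum(touches) >= 3)
    stop("no boundary found: grown region touches ", sum(touches),
         " of 6 cube faces; tighten the HU window or the cube")
  noduleMask(m, spacing = volume@spacing, origin = volume@origin)
}

#' Clean a segmentation mask
#'
#' Keeps the largest 6-connected component and fills interior cavities
#' (background components not connected to the grid border). An automated
#' surrogate for manual removal of intruding structures. Idempotent.
#'
#' @param mask a \linkS4class{NoduleMask}.
#' @return a cleaned \linkS4class{NoduleMask}.
#' @export
cleanMask <- function(mask) {
  d <- dim(mask@values)
  if (!any(mask@values)) stop("validation error: empty mask")
  lab <- array(.cpp_label6(as.logical(mask@values), d), d)
  sizes <- tabulate(lab[lab > 0])
  keep <- lab == which.max(sizes)
  ## fill cavities: background components that do not touch the border
  bg <- .cpp_label6(!keep, d)
  bg <- array(bg, d)
  border <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ],
                     bg[, , c(1, d[3])]))
  border <- border[border > 0]
  filled <- keep | !(bg %in% border) & bg > 0
  filled <- array(filled, d)
  noduleMask(filled, spacing = mask@spacing, origin = mask@origin)
}

#' Nodule-free surrounding shell
#'
#' Voxels whose Euclidean distance to the nodule surface lies in
#' (0, distanceMm], computed on the anisotropic grid in mm, optionally
#' intersected with a lung mask. The shell is disjoint from the nodule by
#' construction and is the region over which the surrounding-lung parenchymal
#' features are computed (default 10 mm).
#'
#' @param mask a \linkS4class{NoduleMask}.
#' @param distanceMm shell thickness in mm (> 0).
#' @param lungMask optional \linkS4class{NoduleMask} restricting the shell to
#'   lung voxels.
#' @return a \linkS4class{NoduleMask} of the shell.
#' @export
surroundShell <- function(mask, distanceMm = 10, lungMask = NULL) {
  if (distanceMm <= 0) stop("validation error: distanceMm must be > 0")
  if (!any(mask@values)) stop("validation error: empty mask")
  d <- dim(mask@values)
  ## distance to the nearest mask voxel centre (exact anisotropic EDT);
  ## the shell converges to the continuum (0, distanceMm] band as spacing
  ## shrinks
  d2 <- .cpp_edt_sq(as.logical(mask@values), d, mask@spacing)
  shell <- array(d2 > 0 & d2 <= distanceMm^2, d)
  if (!is.null(lungMask)) {
    stopifnotSameGrid(mask, lungMask)
    shell <- shell & lungMask@values
  }
  noduleMask(shell, spacing = mask@spacing, origin = mask@origin)
}
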
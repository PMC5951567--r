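#' Read a CT volume
#'
#' Reads a NIfTI volume into a \linkS4class{VoxelVolume}, taking spacing and
#' origin from the image transform. DICOM series input is not supported by
#' this build; convert series to NIfTI first.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param format input format; only \code{"nifti"} is supported.
#' @return a \linkS4class{VoxelVolume}.
#' @export
loadVolume <- function(path, format = c("nifti", "dicom_series")) {
  format <- match.arg(format)
  if (format == "dicom_series")
    stop("format error: DICOM series reading is not supported; ",
         "convert the series to NIfTI")
  if (!file.exists(path)) stop("no readable images at '", path, "'")
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("format error: expected a 3D volume")
  arr <- array(as.numeric(img), dim = dim(img))
  x <- RNifti::xform(img)
  spacing <- abs(diag(x)[1:3])
  if (any(spacing <= 0)) spacing <- RNifti::pixdim(img)[1:3]
  voxelVolume(arr, spacing = spacing, origin = x[1:3, 4])
}

#' Read a binary mask
#'
#' @param path path to a NIfTI file holding a 0/1 grid.
#' @return a \linkS4class{NoduleMask}.
#' @export
loadMask <- function(path) {
  v <- loadVolume(path)
  noduleMask(v@values > 0.5, spacing = v@spacing, origin = v@origin)
}

#' Write a volume or mask as NIfTI
#'
#' Spacing and origin are stored in the sform so that
#' \code{\link{loadVolume}} round-trips them exactly. Masks are written as
#' 0/1 integers.
#'
#' @param x a \linkS4class{VoxelVolume} or \linkS4class{NoduleMask}.
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeVolume <- function(x, path) {
  arr <- if (is(x, "NoduleMask")) array(as.integer(x@values), dim(x@values))
         else x@values
  img <- RNifti::asNifti(arr)
  m <- diag(4)
  diag(m)[1:3] <- x@spacing
  m[1:3, 4] <- x@origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read or write a carina landmark
#'
#' The landmark is stored as JSON \code{{"x": ..., "y": ..., "z": ...}} in
#' world mm.
#'
#' @param path JSON file path.
#' @param carina numeric(3) world coordinate in mm.
#' @return \code{loadCarina} returns numeric(3).
#' @export
loadCarina <- function(path) {
  j <- jsonlite::read_json(path)
  as.numeric(c(j$x, j$y, j$z))
}

#' @rdname loadCarina
#' @export
writeCarina <- function(carina, path) {
  jsonlite::write_json(list(x = carina[1], y = carina[2], z = carina[3]),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
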
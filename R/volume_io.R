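#' Read a scalar field from a NIfTI-1 raster volume
#'
#' Reads a 3-D volume with voxel spacing taken from the NIfTI `pixdim`
#' header (assumed to be in mm) and the origin from the quaternion/affine
#' translation. Values, spacing and origin round-trip losslessly through
#' [write_volume()].
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [scalar_field()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3) {
    stop("expected a 3-D volume, got ", length(d), " dimensions", call. = FALSE)
  }
  xf <- RNifti::xform(img)
  spacing <- sqrt(colSums(xf[1:3, 1:3]^2))
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    spacing <- RNifti::pixdim(img)[1:3]
  }
  if (length(spacing) < 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("volume header is missing positive voxel spacing", call. = FALSE)
  }
  origin <- as.numeric(xf[1:3, 4])
  grid <- make_grid(d, spacing[1:3], origin)
  scalar_field(grid, array(as.numeric(img), dim = d))
}

#' Write a scalar field as a NIfTI-1 raster volume
#'
#' @param field A [scalar_field()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(field, path) {
  stopifnot(inherits(field, "scalar_field"))
  g <- field$grid
  aff <- diag(c(g$spacing, 1))
  aff[1:3, 4] <- g$origin
  img <- RNifti::asNifti(field$values, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
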
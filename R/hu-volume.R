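#' CT volume in Hounsfield units
#'
#' Container for a 3D scalar field of Hounsfield units (HU) with voxel
#' geometry. Water is 0 HU; pure cortical bone sits near `hu_bone` (2000 HU
#' for the study property set). All skull models derive from this object.
#'
#' @param values 3D numeric array of HU
#' @param spacing per-axis voxel size in mm (length 3, or scalar)
#' @param origin world position (mm) of the centre of voxel `(1,1,1)`;
#'   default centres the volume on the origin
#' @param orientation 3x3 proper rotation, voxel axes to world axes
#' @return object of class `hu_volume`
#' @export
hu_volume <- function(values, spacing, origin = NULL, orientation = diag(3)) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (!all(is.finite(values))) stop("HU values must be finite")
  spacing <- rep_len(as.numeric(spacing), 3)
  stopifnot(all(is.finite(spacing)), all(spacing > 0))
  check_rotation(orientation)
  if (is.null(origin)) {
    origin <- as.numeric(-orientation %*% ((dim(values) - 1) * spacing / 2))
  }
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin), orientation = orientation),
            class = "hu_volume")
}

#' @export
print.hu_volume <- function(x, ...) {
  cat("<hu_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm; HU range [", round(min(x$values)), ", ", round(max(x$values)),
      "]\n", sep = "")
  invisible(x)
}

#' Read a CT volume from a NIfTI-1 file
#'
#' The stored intensities are taken to already be Hounsfield units (any
#' scl_slope/scl_inter rescaling is applied by the reader). The NIfTI affine
#' supplies spacing, origin and orientation.
#'
#' @param path NIfTI file (.nii or .nii.gz)
#' @return an [hu_volume()]
#' @export
read_hu_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  R <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(R^2))
  orientation <- sweep(R, 2, spacing, "/")
  hu_volume(unclass(as.array(img)), spacing = spacing,
            origin = aff[1:3, 4], orientation = orientation)
}

#' Write a volume (array plus geometry) to NIfTI-1
#'
#' @param values 3D array (complex volumes are written as magnitude)
#' @param geom any object carrying `spacing`, `origin`, `orientation`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_volume_nifti <- function(values, geom, path) {
  if (is.complex(values)) values <- Mod(values)
  aff <- rbind(cbind(sweep(geom$orientation, 2, geom$spacing, "*"),
                     geom$origin), c(0, 0, 0, 1))
  img <- RNifti::asNifti(array(as.numeric(values), dim = dim(values)))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}
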
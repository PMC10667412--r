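#' Read a volume from NIfTI or a DICOM series
#'
#' Accepts either a NIfTI file (`.nii` / `.nii.gz`) or a directory holding
#' one DICOM series. Intensities are returned in HU (DICOM stored values
#' are mapped through RescaleSlope/Intercept) in the package's canonical
#' axis order (x, y, z; 0-based voxel (0,0,0) at the origin).
#'
#' @param path NIfTI file or DICOM directory.
#' @return A [cta_volume()].
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path)) stop("no such file: ", path)
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop("expected a NIfTI file or a DICOM directory: ", path)
  img <- RNifti::readNifti(path)
  h <- RNifti::niftiHeader(img)
  cta_volume(as.array(img), spacing = RNifti::pixdim(img)[1:3],
             origin = c(h$qoffset_x, h$qoffset_y, h$qoffset_z))
}

#' Write a volume or label map as NIfTI
#'
#' Volumes are written as float32, label maps as int16; spacing and origin
#' are stored in the header. The NIfTI round trip is lossless.
#'
#' @param x a [cta_volume()] or [cta_labelmap()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "cta_volume")) {
    arr <- x$intensities; dt <- "auto"
  } else if (inherits(x, "cta_labelmap")) {
    arr <- x$labels; dt <- "int16"
  } else stop("x must be a cta_volume or cta_labelmap")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing
  img <- RNifti::asNifti(img, list(qoffset_x = x$origin[1],
                                   qoffset_y = x$origin[2],
                                   qoffset_z = x$origin[3],
                                   qform_code = 1))
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Read a label map from NIfTI
#'
#' @param path NIfTI file with integer labels in {0, 1, 2}.
#' @return A [cta_labelmap()].
#' @export
read_labelmap <- function(path) {
  img <- RNifti::readNifti(path)
  h <- RNifti::niftiHeader(img)
  cta_labelmap(as.array(img), spacing = RNifti::pixdim(img)[1:3],
               origin = c(h$qoffset_x, h$qoffset_y, h$qoffset_z))
}
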
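#' Blank everything outside the segmentation to air
#'
#' Produces the focused-view volume: voxels whose label is 1 (brain and
#' cranial cavity) or 2 (extracranial arteries) keep their original HU
#' value bit-exactly; every background voxel is set to exactly -1000 HU.
#' Geometry metadata is preserved and the operation is idempotent.
#'
#' @param volume a [cta_volume()].
#' @param labels an aligned [cta_labelmap()].
#' @return The focused-view [cta_volume()].
#' @export
apply_focus_mask <- function(volume, labels) {
  if (!inherits(volume, "cta_volume")) stop("volume must be a cta_volume")
  if (!inherits(labels, "cta_labelmap")) stop("labels must be a cta_labelmap")
  check_aligned(volume, labels)
  out <- volume$intensities
  out[labels$labels == 0L] <- -1000
  cta_volume(out, spacing = volume$spacing, origin = volume$origin,
             orientation = volume$orientation)
}

# nearest-neighbour mapping of a resampled-grid label array back onto the
# native in-plane grid (z axis is never resampled)
labels_to_native <- function(lab_rs, rs_spacing, native_dim, native_spacing) {
  ix <- ((seq_len(native_dim[1]) - 0.5) * native_spacing[1]) /
    rs_spacing[1] + 0.5
  iy <- ((seq_len(native_dim[2]) - 0.5) * native_spacing[2]) /
    rs_spacing[2] + 0.5
  out <- resample_xy_grid(lab_rs, ix, iy, nearest = TRUE)
  storage.mode(out) <- "integer"
  out
}

# full segmentation pipeline shared by predict methods and convert_case
segment_volume <- function(object, volume, overlap = 0.5) {
  pre <- object$preproc
  if (is.null(pre)) pre <- preproc_config(1.0, "z_norm")
  cfg <- if (inherits(object, "cta_ensemble")) object$cfg
  else object$network$cfg
  rs <- resample_inplane(volume, pre$inplane_spacing_mm)
  nz <- normalize_volume(rs$volume, pre$normalization)
  probs <- sliding_window_predict(object, nz$data, cfg$window_shape,
                                  overlap_fraction = overlap,
                                  pad_value = nz$stats$pad_value)
  lab_rs <- labels_from_probabilities(probs, spacing = rs$volume$spacing)
  native <- labels_to_native(lab_rs$labels, rs$volume$spacing,
                             dim(volume$intensities), volume$spacing)
  list(labels = cta_labelmap(native, spacing = volume$spacing,
                             origin = volume$origin),
       probs = probs, probs_spacing = rs$volume$spacing)
}

#' End-to-end conversion of one CTA case to focused view
#'
#' Reads a volume (NIfTI or DICOM series), segments it with a trained
#' model or ensemble via sliding-window prediction, maps the predicted
#' labels back onto the native grid, blanks all background to -1000 HU,
#' and writes the focused-view DICOM series plus the label map as NIfTI.
#' Stage failures are reported with the failing stage's name.
#'
#' @param bundle a `cta_segmenter` or `cta_ensemble`.
#' @param in_path input NIfTI file or DICOM directory.
#' @param out_path output directory.
#' @param overlap sliding-window overlap fraction, default 0.5.
#' @return List: `dicom_files`, `labels_path`, `seconds` (wall time), and
#'   `voxel_counts` per class.
#' @export
convert_case <- function(bundle, in_path, out_path, overlap = 0.5) {
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  volume <- stage("volio", read_volume(in_path))
  seg <- stage("infer", segment_volume(bundle, volume, overlap))
  focused <- stage("focusedview", apply_focus_mask(volume, seg$labels))
  dir.create(out_path, recursive = TRUE, showWarnings = FALSE)
  files <- stage("volio",
                 write_focused_dicom(focused, series_meta(),
                                     file.path(out_path, "focused_dicom")))
  labels_path <- file.path(out_path, "labels.nii.gz")
  stage("volio", write_volume(seg$labels, labels_path))
  counts <- tabulate(seg$labels$labels + 1L, nbins = 3L)
  list(dicom_files = files, labels_path = labels_path,
       seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
       voxel_counts = c(background = counts[1], brain_cavity = counts[2],
                        extracranial_arteries = counts[3]))
}
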
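#' Volumetric image container
#'
#' A `cta_volume` holds a 3D scalar field of CT intensities in Hounsfield
#' units (HU) together with its geometry: per-axis voxel spacing in mm,
#' origin in mm, and an anatomical axis-orientation code. The in-memory axis
#' order is the package-wide canonical one: x (left-right), y
#' (anterior-posterior), z (inferior-superior), 0-based voxel `(0,0,0)` at
#' the origin. All modules assume this convention.
#'
#' Intensities are clamped to the representable CT range `[-1024, 3071]` at
#' construction; air is -1000 HU, water 0, dense bone well above 1000.
#'
#' @param intensities 3D numeric array of HU values.
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin numeric length-3, position of voxel (0,0,0) in mm.
#' @param orientation character axis code, default "LPS"-style `"RAS"`.
#' @return An object of class `cta_volume`.
#' @examples
#' v <- cta_volume(array(-1000, c(16, 16, 16)), spacing = c(1, 1, 2))
#' dim(v$intensities)
#' @export
cta_volume <- function(intensities, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0), orientation = "RAS") {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values (mm)")
  d <- dim(intensities)
  intensities <- as.double(intensities)   # strip foreign attributes
  dim(intensities) <- d
  intensities[intensities < -1024] <- -1024
  intensities[intensities > 3071] <- 3071
  structure(
    list(intensities = intensities, spacing = spacing, origin = origin,
         orientation = orientation),
    class = "cta_volume")
}

#' Two-class label map container
#'
#' A `cta_labelmap` is a 3D integer field aligned voxel-for-voxel with a
#' [cta_volume()]. Values follow the focused-view annotation protocol:
#' 0 = background, 1 = brain and cranial cavity (including intracranial
#' vessel lumina), 2 = extracranial stroke-related arteries (aortic arch to
#' skull base). Classes 1 and 2 are disjoint by definition.
#'
#' @param labels 3D array with values in {0, 1, 2}.
#' @param spacing,origin,orientation geometry, as in [cta_volume()].
#' @return An object of class `cta_labelmap`.
#' @export
cta_labelmap <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         orientation = "RAS") {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  d <- dim(labels)
  labels <- as.integer(labels)            # strip foreign attributes
  dim(labels) <- d
  if (!all(labels %in% 0:2))
    stop("labels must take values in {0, 1, 2}")
  structure(
    list(labels = labels, spacing = spacing, origin = as.numeric(origin),
         orientation = orientation),
    class = "cta_labelmap")
}

#' @export
print.cta_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<cta_volume> %d x %d x %d voxels, spacing %s mm, HU range [%.0f, %.0f]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = " x "),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
print.cta_labelmap <- function(x, ...) {
  d <- dim(x$labels)
  tb <- tabulate(x$labels + 1L, nbins = 3L)
  cat(sprintf("<cta_labelmap> %d x %d x %d voxels; background %d, brain/cavity %d, extracranial arteries %d\n",
              d[1], d[2], d[3], tb[1], tb[2], tb[3]))
  invisible(x)
}

# shared geometry check used wherever a volume and labels must align
check_aligned <- function(volume, labels, tol = 1e-6) {
  if (!identical(dim(volume$intensities), dim(labels$labels)))
    stop("volume and label map shapes differ")
  if (max(abs(volume$spacing - labels$spacing)) > tol)
    stop("volume and label map spacings differ")
  invisible(TRUE)
}
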
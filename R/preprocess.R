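#' Preprocessing configuration
#'
#' In-plane target spacing and intensity normalization strategy for the
#' training/inference pipeline. The spacing is restricted to the searched
#' set {0.5, 0.7, 1.0} mm; the through-plane axis is never resampled.
#' Normalization is either `z_norm` (per-volume standardization over all
#' voxels) or `divide_by_1000`.
#'
#' @param inplane_spacing_mm one of 0.5, 0.7, 1.0.
#' @param normalization `"z_norm"` or `"divide_by_1000"`.
#' @return An object of class `preproc_config`.
#' @export
preproc_config <- function(inplane_spacing_mm = 0.7,
                           normalization = c("z_norm", "divide_by_1000")) {
  inplane_spacing_mm <- as.numeric(inplane_spacing_mm)
  if (!inplane_spacing_mm %in% c(0.5, 0.7, 1.0))
    stop("inplane_spacing_mm must be one of 0.5, 0.7, 1.0")
  normalization <- match.arg(normalization)
  structure(list(inplane_spacing_mm = inplane_spacing_mm,
                 normalization = normalization),
            class = "preproc_config")
}

#' Augmentation configuration
#'
#' Frequencies (application probabilities) for in-plane rotation,
#' out-of-plane tilt, and additive Gaussian noise, plus the noise level.
#' The rotation/tilt magnitudes are drawn uniformly from
#' `[-max_deg, +max_deg]`; the noise factor is the noise standard deviation
#' in post-normalization intensity units.
#'
#' @param rotation_freq,tilt_freq,noise_freq application probabilities in
#'   `[0, 1]` (the searched ranges are 0-0.5 for rotation/tilt and 0-0.7
#'   for noise).
#' @param noise_factor additive-noise sd in normalized units, >= 0.
#' @param rotation_max_deg,tilt_max_deg maximum rotation angles, degrees.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(rotation_freq = 0.25, tilt_freq = 0.04,
                           noise_freq = 0.60, noise_factor = 0.003,
                           rotation_max_deg = 15, tilt_max_deg = 5) {
  for (f in c(rotation_freq, tilt_freq, noise_freq))
    if (f < 0 || f > 1) stop("augmentation frequencies must lie in [0,1]")
  if (noise_factor < 0) stop("noise_factor must be >= 0")
  if (rotation_max_deg < 0 || tilt_max_deg < 0)
    stop("rotation angles must be >= 0")
  structure(list(rotation_freq = rotation_freq, tilt_freq = tilt_freq,
                 noise_freq = noise_freq, noise_factor = noise_factor,
                 rotation_max_deg = rotation_max_deg,
                 tilt_max_deg = tilt_max_deg),
            class = "augment_config")
}

# Bilinear resampling of all xy-slices onto target in-plane coordinates
# given as fractional source indices (vectors ix over new X, iy over new Y).
# 'nearest' switches to nearest-neighbour gathering (labels).
resample_xy_grid <- function(arr, ix, iy, nearest = FALSE, fill = 0) {
  d <- dim(arr)
  nz <- prod(d[-(1:2)])
  m <- matrix(arr, d[1] * d[2], nz)
  nx <- length(ix); ny <- length(iy)
  if (nearest) {
    jx <- pmin(pmax(round(ix), 1L), d[1])
    jy <- pmin(pmax(round(iy), 1L), d[2])
    idx <- as.vector(outer(jx, (jy - 1L) * d[1], "+"))
    out <- m[idx, , drop = FALSE]
  } else {
    x0 <- pmin(pmax(floor(ix), 1L), d[1] - 1L); fx <- pmin(pmax(ix - x0, 0), 1)
    y0 <- pmin(pmax(floor(iy), 1L), d[2] - 1L); fy <- pmin(pmax(iy - y0, 0), 1)
    FX <- matrix(fx, nx, ny); FY <- matrix(fy, nx, ny, byrow = TRUE)
    i00 <- as.vector(outer(x0, (y0 - 1L) * d[1], "+"))
    w00 <- as.vector((1 - FX) * (1 - FY)); w10 <- as.vector(FX * (1 - FY))
    w01 <- as.vector((1 - FX) * FY); w11 <- as.vector(FX * FY)
    out <- m[i00, , drop = FALSE] * w00 + m[i00 + 1L, , drop = FALSE] * w10 +
      m[i00 + d[1], , drop = FALSE] * w01 +
      m[i00 + d[1] + 1L, , drop = FALSE] * w11
  }
  array(out, c(nx, ny, d[-(1:2)]))
}

#' Resample a volume in-plane
#'
#' Resamples the x/y axes of a volume to the target isotropic in-plane
#' spacing; the through-plane axis is left untouched. The image is
#' interpolated bilinearly within each slice; labels, if given, by nearest
#' neighbour (their value set is preserved).
#'
#' @param volume a [cta_volume()].
#' @param target_mm target in-plane spacing, > 0.
#' @param labels optional aligned [cta_labelmap()].
#' @return `list(volume, labels)`; `labels` is `NULL` when not supplied.
#' @export
resample_inplane <- function(volume, target_mm, labels = NULL) {
  if (length(target_mm) != 1L || !is.finite(target_mm) || target_mm <= 0)
    stop("target_mm must be a positive scalar")
  if (!is.null(labels)) check_aligned(volume, labels)
  sp <- volume$spacing
  if (abs(sp[1] - target_mm) < 1e-9 && abs(sp[2] - target_mm) < 1e-9)
    return(list(volume = volume, labels = labels))
  d <- dim(volume$intensities)
  nx <- max(2L, round(d[1] * sp[1] / target_mm))
  ny <- max(2L, round(d[2] * sp[2] / target_mm))
  # voxel-centre alignment: new centre c maps to source index
  ix <- ((seq_len(nx) - 0.5) * target_mm) / sp[1] + 0.5
  iy <- ((seq_len(ny) - 0.5) * target_mm) / sp[2] + 0.5
  newsp <- c(target_mm, target_mm, sp[3])
  vol <- cta_volume(resample_xy_grid(volume$intensities, ix, iy),
                    spacing = newsp, origin = volume$origin,
                    orientation = volume$orientation)
  lab <- NULL
  if (!is.null(labels))
    lab <- cta_labelmap(resample_xy_grid(labels$labels, ix, iy,
                                         nearest = TRUE),
                        spacing = newsp, origin = labels$origin,
                        orientation = labels$orientation)
  list(volume = vol, labels = lab)
}

#' Normalize a volume's intensities
#'
#' `z_norm` standardizes by the volume's own mean and standard deviation
#' over all voxels (computed once, before any cropping, so inference
#' applies the identical transform); `divide_by_1000` scales by 1/1000.
#'
#' @param volume a [cta_volume()].
#' @param strategy `"z_norm"` or `"divide_by_1000"`.
#' @return A list: `data` (3D array in normalized units), `stats` (named
#'   list recording the strategy and the transform constants, including
#'   `pad_value`, the normalized image of -1000 HU used for padding).
#' @export
normalize_volume <- function(volume, strategy = c("z_norm", "divide_by_1000")) {
  strategy <- match.arg(strategy)
  x <- volume$intensities
  if (strategy == "z_norm") {
    mu <- mean(x); sdv <- stats::sd(as.vector(x))
    if (!is.finite(sdv) || sdv == 0)
      stop("z_norm undefined: volume has zero intensity variance")
    list(data = (x - mu) / sdv,
         stats = list(strategy = "z_norm", mean = mu, sd = sdv,
                      pad_value = (-1000 - mu) / sdv))
  } else {
    list(data = x / 1000,
         stats = list(strategy = "divide_by_1000", pad_value = -1))
  }
}

# pad a (possibly) too-small array up to the window with a constant
pad_to_window <- function(arr, window, value) {
  d <- dim(arr)
  if (all(d >= window)) return(arr)
  nd <- pmax(d, window)
  out <- array(value, nd)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
  out
}

#' Sample a random training patch
#'
#' Draws a window-shaped crop at a uniformly random corner from a
#' normalized volume and its labels. With `reject_background = TRUE`
#' (default), an all-background label patch is re-drawn up to `max_reject`
#' times; the last draw is kept regardless. Volumes smaller than the window
#' are padded with `pad_value` (image) and background (labels).
#'
#' @param data 3D array of normalized intensities.
#' @param labels 3D integer array aligned with `data`.
#' @param window_shape integer length-3 crop shape.
#' @param pad_value padding intensity (normalized image of -1000 HU).
#' @param reject_background logical; re-sample all-background crops.
#' @param max_reject maximum re-draws, default 10.
#' @return List `image` and `labels`, both of `window_shape`.
#' @export
sample_patch <- function(data, labels, window_shape, pad_value = -1,
                         reject_background = TRUE, max_reject = 10L) {
  window_shape <- as.integer(window_shape)
  data <- pad_to_window(data, window_shape, pad_value)
  labels <- pad_to_window(labels, window_shape, 0L)
  d <- dim(data)
  if (any(window_shape > d)) stop("window larger than padded volume")
  for (try in seq_len(max_reject + 1L)) {
    corner <- vapply(1:3, function(a) {
      if (d[a] == window_shape[a]) 1L
      else sample.int(d[a] - window_shape[a] + 1L, 1L)
    }, 0L)
    ix <- lapply(1:3, function(a) corner[a] + seq_len(window_shape[a]) - 1L)
    lp <- labels[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
    if (!reject_background || any(lp != 0L) || try > max_reject) break
  }
  list(image = data[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
       labels = lp)
}

# rotate all slices of a 3D array about the in-plane centre by 'deg';
# axes picks which two dims form the rotation plane (c(1,2) or c(2,3))
rotate_plane <- function(arr, deg, axes = c(1, 2), nearest = FALSE,
                         fill = 0) {
  d <- dim(arr)
  perm <- c(axes, setdiff(1:3, axes))
  x <- aperm(arr, perm)
  dd <- dim(x)
  th <- deg * pi / 180
  cx <- (dd[1] + 1) / 2; cy <- (dd[2] + 1) / 2
  gx <- rep(seq_len(dd[1]), times = dd[2]) - cx
  gy <- rep(seq_len(dd[2]), each = dd[1]) - cy
  sx <- cos(th) * gx + sin(th) * gy + cx
  sy <- -sin(th) * gx + cos(th) * gy + cy
  m <- matrix(x, dd[1] * dd[2], dd[3])
  tol <- 1e-6   # keep exact-boundary coordinates of near-zero rotations
  inside <- sx >= 1 - tol & sx <= dd[1] + tol &
    sy >= 1 - tol & sy <= dd[2] + tol
  if (nearest) {
    jx <- pmin(pmax(round(sx), 1L), dd[1])
    jy <- pmin(pmax(round(sy), 1L), dd[2])
    out <- m[jx + (jy - 1L) * dd[1], , drop = FALSE]
  } else {
    x0 <- pmin(pmax(floor(sx), 1L), dd[1] - 1L); fx <- sx - x0
    y0 <- pmin(pmax(floor(sy), 1L), dd[2] - 1L); fy <- sy - y0
    i00 <- x0 + (y0 - 1L) * dd[1]
    out <- m[i00, , drop = FALSE] * ((1 - fx) * (1 - fy)) +
      m[i00 + 1L, , drop = FALSE] * (fx * (1 - fy)) +
      m[i00 + dd[1], , drop = FALSE] * ((1 - fx) * fy) +
      m[i00 + dd[1] + 1L, , drop = FALSE] * (fx * fy)
  }
  out[!inside, ] <- fill
  aperm(array(out, dd), order(perm))
}

#' Augment a training patch
#'
#' Independently, with the configured frequencies: an in-plane rotation by
#' an angle uniform in `[-rotation_max_deg, rotation_max_deg]` (image
#' bilinear, labels nearest-neighbour), a small out-of-plane tilt likewise,
#' and additive Gaussian noise of sd `noise_factor` (normalized units)
#' applied to the image only. Label values never leave {0, 1, 2} and the
#' patch shape is unchanged.
#'
#' @param pair list with `image` and `labels` as from [sample_patch()].
#' @param cfg an [augment_config()].
#' @param pad_value fill intensity for voxels rotated in from outside.
#' @return An augmented `list(image, labels)`.
#' @export
augment_patch <- function(pair, cfg, pad_value = -1) {
  if (!inherits(cfg, "augment_config")) stop("cfg must be an augment_config")
  img <- pair$image; lab <- pair$labels
  if (stats::runif(1) < cfg$rotation_freq) {
    a <- stats::runif(1, -cfg$rotation_max_deg, cfg$rotation_max_deg)
    img <- rotate_plane(img, a, c(1, 2), fill = pad_value)
    lab <- rotate_plane(lab, a, c(1, 2), nearest = TRUE, fill = 0L)
  }
  if (stats::runif(1) < cfg$tilt_freq) {
    a <- stats::runif(1, -cfg$tilt_max_deg, cfg$tilt_max_deg)
    img <- rotate_plane(img, a, c(2, 3), fill = pad_value)
    lab <- rotate_plane(lab, a, c(2, 3), nearest = TRUE, fill = 0L)
  }
  if (stats::runif(1) < cfg$noise_freq && cfg$noise_factor > 0)
    img <- img + stats::rnorm(length(img), 0, cfg$noise_factor)
  storage.mode(lab) <- "integer"
  list(image = img, labels = lab)
}
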
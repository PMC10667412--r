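#' Specification for a synthetic head-and-neck CTA phantom
#'
#' Defines the geometry, materials, and randomness of a synthetic
#' CT-angiography phantom: an air background at -1000 HU, a soft-tissue
#' neck column with a vertebra-like bone column and spinal canal, a bone
#' skull shell enclosing a brain ellipsoid, and contrast-opacified tortuous
#' vessels running from the inferior "aortic arch" region through the neck
#' to a skull-base opening and on into the cranial cavity. The paired
#' ground-truth label map marks the cranial-cavity interior as class 1 and
#' the extracranial vessel lumina as class 2, mirroring the two-step
#' annotation protocol (cavity-level first, artery-level second).
#'
#' Default material means (HU): air -1000, soft tissue 40, brain 30,
#' bone 1000, opacified vessel 400 — plausible CTA values, freely
#' configurable. The default additive noise of 10 HU is typical of a
#' contrast head/neck acquisition.
#'
#' @param grid_shape integer length-3, voxels per axis (each >= 16).
#' @param spacing_mm numeric length-3 voxel size in mm, all > 0.
#' @param hu_materials named list mapping roles `air`, `soft_tissue`,
#'   `brain`, `bone`, `vessel` to `c(mean, sd)` in HU. Air mean is fixed at
#'   -1000 and the vessel mean must exceed the soft-tissue mean.
#' @param vessel_count number of tortuous vessels (>= 0).
#' @param tortuosity dimensionless amplitude of centerline undulation
#'   (0 = straight; 1 = strongly tortuous, with a helical twist near the
#'   skull base).
#' @param vessel_radius_mm length-2 range from which each vessel radius is
#'   drawn.
#' @param stenosis_prob probability in `[0,1]` that a vessel receives a
#'   focal narrowing.
#' @param noise_sd_hu standard deviation of additive Gaussian noise, HU.
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 120),
                         spacing_mm = c(1, 1, 1),
                         hu_materials = list(
                           air = c(-1000, 0), soft_tissue = c(40, 0),
                           brain = c(30, 0), bone = c(1000, 0),
                           vessel = c(400, 0)),
                         vessel_count = 4,
                         tortuosity = 0.5,
                         vessel_radius_mm = c(2, 3),
                         stenosis_prob = 0.2,
                         noise_sd_hu = 10,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(is.na(grid_shape)) || any(grid_shape < 16L))
    stop("invalid phantom spec: grid_shape must be three integers >= 16")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("invalid phantom spec: spacing_mm must be three positive values")
  roles <- c("air", "soft_tissue", "brain", "bone", "vessel")
  if (!all(roles %in% names(hu_materials)))
    stop("invalid phantom spec: hu_materials must name ",
         paste(roles, collapse = ", "))
  for (r in roles) {
    m <- hu_materials[[r]]
    if (length(m) != 2L || !all(is.finite(m)) || m[2] < 0)
      stop("invalid phantom spec: hu_materials entry '", r,
           "' must be c(mean, sd) with sd >= 0")
  }
  if (hu_materials$air[1] != -1000)
    stop("invalid phantom spec: hu_materials air mean is fixed at -1000")
  if (hu_materials$vessel[1] <= hu_materials$soft_tissue[1])
    stop("invalid phantom spec: hu_materials vessel mean must exceed soft-tissue mean")
  if (length(vessel_count) != 1L || is.na(vessel_count) || vessel_count < 0)
    stop("invalid phantom spec: vessel_count must be a non-negative count")
  if (length(tortuosity) != 1L || !is.finite(tortuosity) || tortuosity < 0)
    stop("invalid phantom spec: tortuosity must be a non-negative scalar")
  vessel_radius_mm <- as.numeric(vessel_radius_mm)
  if (length(vessel_radius_mm) != 2L || any(vessel_radius_mm <= 0) ||
      vessel_radius_mm[2] < vessel_radius_mm[1])
    stop("invalid phantom spec: vessel_radius_mm must be an increasing positive range")
  if (length(stenosis_prob) != 1L || is.na(stenosis_prob) ||
      stenosis_prob < 0 || stenosis_prob > 1)
    stop("invalid phantom spec: stenosis_prob must lie in [0,1]")
  if (length(noise_sd_hu) != 1L || !is.finite(noise_sd_hu) || noise_sd_hu < 0)
    stop("invalid phantom spec: noise_sd_hu must be >= 0")
  structure(
    list(grid_shape = grid_shape, spacing_mm = spacing_mm,
         hu_materials = hu_materials,
         vessel_count = as.integer(vessel_count), tortuosity = tortuosity,
         vessel_radius_mm = vessel_radius_mm, stenosis_prob = stenosis_prob,
         noise_sd_hu = noise_sd_hu, seed = as.integer(seed)),
    class = "phantom_spec")
}

# Evaluate an expression with a private RNG stream, restoring global state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic CTA phantom and its ground-truth labels
#'
#' Renders the phantom described by a [phantom_spec()]: air background,
#' soft-tissue body contour, vertebra-like bone column with spinal canal,
#' skull shell with a skull-base opening, brain-filled cranial cavity, and
#' tortuous contrast-opacified vessels. Vessel centerlines are cubic-spline
#' curves through jittered waypoints with an optional helical perturbation
#' near the skull base, so vessels pass close to bone (vertebrae and skull
#' base) — the configuration hardest to segment.
#'
#' The label map marks the cranial-cavity interior (brain plus intracranial
#' vessel lumina) as class 1 and extracranial vessel lumina as class 2;
#' the two are disjoint by construction.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (a [cta_volume()]) and `labels`
#'   (a [cta_labelmap()]). The attribute `"vessels"` carries, per vessel, a
#'   data frame of the dense centerline samples (`x`,`y`,`z` in mm, radius
#'   `r` in mm, and step length `ds` in mm) for analytic cross-checks.
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 48), seed = 7))
#' table(ph$labels$labels)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  gs <- spec$grid_shape; sp <- spec$spacing_mm
  ext <- gs * sp                      # physical extent, mm
  hu <- lapply(spec$hu_materials, function(m) m[1])
  sds <- lapply(spec$hu_materials, function(m) m[2])

  # physical coordinates of voxel centres
  xs <- (seq_len(gs[1]) - 0.5) * sp[1]
  ys <- (seq_len(gs[2]) - 0.5) * sp[2]
  zs <- (seq_len(gs[3]) - 0.5) * sp[3]
  X <- array(xs, gs)
  Y <- array(rep(ys, each = gs[1]), gs)
  Z <- array(rep(zs, each = gs[1] * gs[2]), gs)

  vol <- array(hu$air, gs)
  lab <- array(0L, gs)

  # head: ellipsoid; neck: elliptic cylinder below the head.
  # proportions mimic a head-and-neck CTA field of view: the cranial
  # cavity spans most of the head width and roughly the upper third in z
  head_c <- c(0.5, 0.5, 0.72) * ext
  head_ax <- c(0.38, 0.40, 0.26) * ext
  head_in <- ((X - head_c[1]) / head_ax[1])^2 +
             ((Y - head_c[2]) / head_ax[2])^2 +
             ((Z - head_c[3]) / head_ax[3])^2 <= 1
  neck_top <- head_c[3]
  neck_in <- (Z <= neck_top) &
    (((X - 0.5 * ext[1]) / (0.26 * ext[1]))^2 +
     ((Y - 0.5 * ext[2]) / (0.26 * ext[2]))^2 <= 1)
  body <- head_in | neck_in
  vol[body] <- hu$soft_tissue

  # skull: ellipsoidal bone shell, brain inside, with a skull-base channel
  sk_ax <- c(0.32, 0.34, 0.20) * ext
  sk_th <- 3                          # shell thickness, mm
  q_out <- ((X - head_c[1]) / sk_ax[1])^2 +
           ((Y - head_c[2]) / sk_ax[2])^2 +
           ((Z - head_c[3]) / sk_ax[3])^2
  in_ax <- pmax(sk_ax - sk_th, sk_ax * 0.5)
  q_in <- ((X - head_c[1]) / in_ax[1])^2 +
          ((Y - head_c[2]) / in_ax[2])^2 +
          ((Z - head_c[3]) / in_ax[3])^2
  cavity <- q_in <= 1
  shell <- (q_out <= 1) & !cavity
  # skull-base opening (foramen-magnum-like): carve a vertical channel
  base_xy <- c(0.5, 0.55) * ext[1:2]
  channel <- sqrt((X - base_xy[1])^2 + (Y - base_xy[2])^2) <= 8 &
    Z < head_c[3]
  vol[shell & !channel] <- hu$bone
  vol[cavity] <- hu$brain
  vol[shell & channel & !cavity] <- hu$soft_tissue
  lab[cavity] <- 1L

  # vertebra-like column with spinal canal, below the skull
  col_xy <- c(0.5, 0.62) * ext[1:2]
  rad_xy <- sqrt((X - col_xy[1])^2 + (Y - col_xy[2])^2)
  below_skull <- Z < (head_c[3] - sk_ax[3])
  segmented <- (Z %% 18) < 14         # vertebral bodies with disc gaps
  vert <- below_skull & segmented & rad_xy <= 9 & rad_xy > 4 & body
  vol[vert] <- hu$bone

  # per-material texture (sd > 0 adds Gaussian heterogeneity)
  tex <- function(mask, sd) {
    n <- sum(mask)
    if (sd > 0 && n > 0) vol[mask] <<- vol[mask] + stats::rnorm(n, 0, sd)
  }
  tex(!body, sds$air); tex(body & !(cavity | shell), sds$soft_tissue)
  tex(cavity, sds$brain); tex(shell | vert, sds$bone)

  # tortuous vessels from the inferior "arch" region to the cranial cavity
  vessels <- list()
  if (spec$vessel_count > 0) {
    for (v in seq_len(spec$vessel_count)) {
      cl <- vessel_centerline(spec, ext, head_c, sk_ax, base_xy)
      r0 <- stats::runif(1, spec$vessel_radius_mm[1], spec$vessel_radius_mm[2])
      r <- rep(r0, nrow(cl))
      if (stats::runif(1) < spec$stenosis_prob) {
        t0 <- stats::runif(1, 0.2, 0.7)
        tt <- seq(0, 1, length.out = nrow(cl))
        r <- r * (1 - 0.6 * exp(-((tt - t0) / 0.05)^2))
      }
      ds <- c(0, sqrt(rowSums(diff(as.matrix(cl))^2)))
      vessels[[v]] <- data.frame(x = cl$x, y = cl$y, z = cl$z, r = r, ds = ds)
      stamped <- stamp_tube(gs, sp, cl, r)
      vvox <- which(stamped)
      vol[vvox] <- hu$vessel +
        if (sds$vessel > 0) stats::rnorm(length(vvox), 0, sds$vessel) else 0
      lab[vvox[!cavity[vvox]]] <- 2L
      lab[vvox[cavity[vvox]]] <- 1L
    }
  }

  volume <- cta_volume(vol, spacing = sp)
  if (spec$noise_sd_hu > 0)
    volume <- apply_noise(volume, spec$noise_sd_hu,
                          seed = spec$seed + 104729L)
  out <- list(volume = volume, labels = cta_labelmap(lab, spacing = sp))
  attr(out, "vessels") <- vessels
  out
}

# Smooth centerline: spline through jittered waypoints from the inferior
# margin to just inside the cranial cavity, with a helical twist near the
# skull base proportional to the tortuosity amplitude.
vessel_centerline <- function(spec, ext, head_c, sk_ax, base_xy) {
  tor <- spec$tortuosity
  start <- c(stats::runif(1, 0.30, 0.70) * ext[1],
             stats::runif(1, 0.32, 0.48) * ext[2], 0)
  entry <- c(base_xy[1] + stats::runif(1, -4, 4),
             base_xy[2] + stats::runif(1, -3, 3),
             head_c[3] - sk_ax[3] + 2)
  end <- c(entry[1], entry[2], min(entry[3] + 0.4 * sk_ax[3], ext[3] - 1))
  nw <- 6
  tt <- seq(0, 1, length.out = nw)
  wx <- start[1] + (entry[1] - start[1]) * tt
  wy <- start[2] + (entry[2] - start[2]) * tt
  wz <- start[3] + (entry[3] - start[3]) * tt
  jit <- function(w) {
    w[2:(nw - 1)] <- w[2:(nw - 1)] + stats::rnorm(nw - 2, 0, tor * 8)
    w
  }
  wx <- jit(wx); wy <- jit(wy)
  step <- 0.4 * min(spec$spacing_mm)
  n <- max(16L, ceiling((entry[3] - start[3]) / step) * 2L)
  ts <- seq(0, 1, length.out = n)
  cx <- stats::spline(tt, wx, xout = ts)$y
  cy <- stats::spline(tt, wy, xout = ts)$y
  cz <- stats::spline(tt, wz, xout = ts)$y
  # helical perturbation over the last quarter of the ascent (skull base)
  near <- ts > 0.75
  if (tor > 0 && any(near)) {
    ph <- stats::runif(1, 0, 2 * pi)
    ang <- (ts[near] - 0.75) / 0.25 * 3 * pi + ph
    amp <- tor * 4 * ((ts[near] - 0.75) / 0.25)
    cx[near] <- cx[near] + amp * cos(ang)
    cy[near] <- cy[near] + amp * sin(ang)
  }
  # straight intracranial continuation
  n2 <- max(4L, ceiling((end[3] - entry[3]) / step))
  data.frame(
    x = c(cx, rep(end[1], n2)),
    y = c(cy, rep(end[2], n2)),
    z = c(cz, seq(entry[3], end[3], length.out = n2)))
}

# Rasterize a tube of per-sample radius r around a dense centerline.
stamp_tube <- function(gs, sp, cl, r) {
  out <- array(FALSE, gs)
  for (i in seq_len(nrow(cl))) {
    p <- c(cl$x[i], cl$y[i], cl$z[i])
    ri <- r[i]
    if (ri <= 0) next
    lo <- pmax(1L, floor((p - ri) / sp - 0.5) + 1L)
    hi <- pmin(gs, ceiling((p + ri) / sp + 0.5))
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    dx2 <- ((ix - 0.5) * sp[1] - p[1])^2
    dy2 <- ((iy - 0.5) * sp[2] - p[2])^2
    dz2 <- ((iz - 0.5) * sp[3] - p[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    out[ix, iy, iz] <- out[ix, iy, iz, drop = FALSE] | (d2 <= ri^2)
  }
  out
}

#' Add Gaussian noise to a volume
#'
#' Adds zero-mean Gaussian noise of the given standard deviation (HU) to
#' every voxel; the result is clipped to the representable CT range. A
#' standard deviation of zero returns the input unchanged.
#'
#' @param volume a [cta_volume()].
#' @param sd_hu noise standard deviation in HU, >= 0.
#' @param seed integer seed; the same seed reproduces the same noise field.
#' @return A [cta_volume()].
#' @export
apply_noise <- function(volume, sd_hu, seed = 1L) {
  if (!inherits(volume, "cta_volume")) stop("volume must be a cta_volume")
  if (length(sd_hu) != 1L || !is.finite(sd_hu) || sd_hu < 0)
    stop("sd_hu must be a non-negative scalar")
  if (sd_hu == 0) return(volume)
  noisy <- with_seed(seed, {
    volume$intensities + stats::rnorm(length(volume$intensities), 0, sd_hu)
  })
  cta_volume(noisy, spacing = volume$spacing, origin = volume$origin,
             orientation = volume$orientation)
}
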
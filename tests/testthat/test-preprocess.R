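test_that("in-plane resampling preserves identity, constants, and volume", {
  ph <- generate_phantom(small_phantom_spec(seed = 3))
  same <- resample_inplane(ph$volume, 1.0, ph$labels)
  expect_identical(same$volume$intensities, ph$volume$intensities)

  const <- cta_volume(array(7, c(20, 20, 10)))
  rs <- resample_inplane(const, 0.5)
  expect_true(all(abs(rs$volume$intensities - 7) < 1e-12))

  fine <- resample_inplane(ph$volume, 0.5, ph$labels)
  d0 <- dim(ph$volume$intensities); d1 <- dim(fine$volume$intensities)
  expect_lte(abs(d1[1] - 2 * d0[1]), 1)
  expect_lte(abs(d1[2] - 2 * d0[2]), 1)
  expect_identical(d1[3], d0[3])
  expect_true(all(fine$labels$labels %in% 0:2))
  # physical class-2 volume conserved within 5%
  v0 <- sum(ph$labels$labels == 2L) * prod(ph$labels$spacing)
  v1 <- sum(fine$labels$labels == 2L) * prod(fine$labels$spacing)
  expect_lt(abs(v1 - v0) / v0, 0.05)
  # physical extent conserved within one voxel per axis
  expect_lt(abs(d1[1] * 0.5 - d0[1] * 1), 1)
  expect_error(resample_inplane(ph$volume, -1), "positive")
})

test_that("normalization strategies satisfy their definitions", {
  ph <- generate_phantom(small_phantom_spec(seed = 5))
  zn <- normalize_volume(ph$volume, "z_norm")
  expect_lt(abs(mean(zn$data)), 1e-6)
  expect_lt(abs(sd(as.vector(zn$data)) - 1), 1e-6)
  # z-norm of already standardized data is the identity
  v2 <- cta_volume(zn$data, spacing = ph$volume$spacing)
  zn2 <- normalize_volume(v2, "z_norm")
  expect_lt(max(abs(zn2$data - zn$data)), 1e-6)

  dv <- normalize_volume(cta_volume(array(-1000, c(16, 16, 16)) +
                                      array(stats::rnorm(4096), c(16, 16, 16))),
                         "divide_by_1000")
  expect_equal(dv$stats$pad_value, -1)
  expect_error(normalize_volume(cta_volume(array(5, c(16, 16, 16))),
                                "z_norm"), "variance")
  # -1000 HU maps to exactly -1
  d1000 <- normalize_volume(cta_volume(array(c(-1000, 500), c(16, 16, 16))),
                            "divide_by_1000")
  expect_equal(d1000$data[1], -1)
})

test_that("patch sampling covers corners uniformly and rejects background", {
  # half-foreground volume: analytic fraction of window corners whose crop
  # contains foreground
  nx <- 24L; w <- 8L
  lab <- array(0L, c(nx, nx, nx))
  lab[13:24, , ] <- 1L
  data <- array(0, c(nx, nx, nx))
  corners <- nx - w + 1L           # per axis
  hit <- sum(vapply(seq_len(corners), function(cx) cx + w - 1L >= 13L, TRUE))
  p_fg <- hit / corners
  set.seed(99)
  draws <- replicate(3000, {
    pp <- sample_patch(data, lab, c(w, w, w), reject_background = FALSE)
    any(pp$labels != 0L)
  })
  se <- sqrt(p_fg * (1 - p_fg) / 3000)
  expect_lt(abs(mean(draws) - p_fg), 3 * se + 1e-9)

  # rejection on: foreground fraction should exceed the unrejected rate
  set.seed(99)
  rej <- replicate(300, {
    pp <- sample_patch(data, lab, c(w, w, w), reject_background = TRUE)
    any(pp$labels != 0L)
  })
  expect_gt(mean(rej), p_fg)

  # full-volume window is the single possible crop
  pp <- sample_patch(data, lab, c(nx, nx, nx))
  expect_identical(pp$image, data)
  expect_identical(pp$labels, lab)

  # reproducible under a fixed seed
  set.seed(7); a <- sample_patch(data, lab, c(w, w, w))
  set.seed(7); b <- sample_patch(data, lab, c(w, w, w))
  expect_identical(a, b)

  expect_error(sample_patch(data, lab, c(64, 8, 8)), NA)  # pads up
  bigger <- sample_patch(data, lab, c(32, 8, 8), pad_value = -1)
  expect_identical(dim(bigger$image), c(32L, 8L, 8L))
})

test_that("augmentation honours frequencies, labels, and noise level", {
  img <- array(0.5, c(40, 40, 24))
  lab <- array(sample(0:2, length(img), TRUE), dim(img))
  pair <- list(image = img, labels = lab)
  none <- augment_patch(pair, augment_config(0, 0, 0, 0))
  expect_identical(none$image, img)
  expect_identical(none$labels, lab)

  set.seed(1)
  rot <- augment_patch(pair, augment_config(1, 0, 0, 0))
  expect_identical(dim(rot$image), dim(img))
  expect_true(all(rot$labels %in% 0:2))

  # rotation by ~0 degrees is the identity within interpolation tolerance
  set.seed(2)
  tiny <- augment_patch(pair, augment_config(1, 0, 0, 0,
                                             rotation_max_deg = 1e-9))
  expect_lt(max(abs(tiny$image - img)), 1e-6)

  # noise sd concentration at the searched optimum level
  set.seed(3)
  big <- list(image = array(0, c(160, 160, 48)),
              labels = array(1L, c(160, 160, 48)))
  noised <- augment_patch(big, augment_config(0, 0, 1, 0.003))
  s <- sd(as.vector(noised$image))
  expect_gt(s, 0.0027)
  expect_lt(s, 0.0033)
})
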
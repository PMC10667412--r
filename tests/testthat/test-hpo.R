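test_that("sampled configurations respect every domain and step rule", {
  sp <- search_space()
  set.seed(31)
  cfgs <- replicate(1000, sample_config(sp), simplify = FALSE)
  xy <- vapply(cfgs, `[[`, 0L, "window_xy")
  expect_true(all(xy %in% c(160L, 192L, 224L, 256L)))
  expect_true(all(vapply(cfgs, `[[`, 0L, "window_z") %in%
                    c(16L, 32L, 48L, 64L)))
  expect_true(all(vapply(cfgs, `[[`, 0L, "batch_size") %in% 1:15))
  lr <- vapply(cfgs, `[[`, 0, "learning_rate")
  expect_true(all(lr >= 1e-4 & lr <= 1e-3))
  nf <- vapply(cfgs, `[[`, 0, "noise_factor")
  expect_true(all(nf >= 1e-4 & nf <= 1e-2))
  rf <- vapply(cfgs, `[[`, 0, "rotation_freq")
  expect_true(all(rf >= 0 & rf <= 0.5))
  expect_true(all(vapply(cfgs, `[[`, "", "normalization") %in%
                    c("z_norm", "divide_by_1000")))
  # log-uniform sampling: roughly half the draws below the geometric mean
  expect_gt(mean(lr < sqrt(1e-4 * 1e-3)), 0.4)
  expect_lt(mean(lr < sqrt(1e-4 * 1e-3)), 0.6)
})

test_that("degenerate spaces collapse to their single point, reproducibly", {
  sp <- search_space(inplane_spacing_mm = 0.7, normalization = "z_norm",
                     window_xy = 160L, window_z = 48L,
                     architecture = "dual_attention_unet", batch_size = 13L,
                     learning_rate = 4e-4, l2_strength = 2e-4,
                     optimizer = "rmsprop", instance_norm = TRUE,
                     rotation_freq = 0.25, tilt_freq = 0.04,
                     noise_freq = 0.6, noise_factor = 0.003)
  cfg <- sample_config(sp)
  expect_equal(unclass(cfg), unclass(default_hyperconfig()),
               tolerance = 1e-12)
  set.seed(5); a <- replicate(10, sample_config(search_space()),
                              simplify = FALSE)
  set.seed(5); b <- replicate(10, sample_config(search_space()),
                              simplify = FALSE)
  expect_identical(a, b)
  expect_error(search_space(bogus = 1), "unknown")
})

test_that("random search recovers a planted optimum within a factor of 2", {
  obj <- function(cfg) -abs(log(cfg$learning_rate) - log(4e-4))
  res <- run_search(search_space(), n_trials = 30, objective = obj,
                    seed = 11)
  expect_identical(nrow(res$trials), 30L)
  expect_gt(res$best$learning_rate, 4e-4 / 2)
  expect_lt(res$best$learning_rate, 4e-4 * 2)
  # the returned best scores at least as well as every recorded trial
  expect_gte(max(res$trials$score, na.rm = TRUE),
             max(res$trials$score[!is.na(res$trials$score)]))
  expect_equal(obj(res$best), max(res$trials$score, na.rm = TRUE))
})

test_that("failed trials are recorded and all-failure aborts", {
  flaky <- local({
    i <- 0
    function(cfg) {
      i <<- i + 1
      if (i %% 2 == 0) stop("boom")
      cfg$learning_rate
    }
  })
  res <- run_search(search_space(), n_trials = 4, objective = flaky,
                    seed = 2)
  expect_identical(nrow(res$trials), 4L)
  expect_identical(sum(is.na(res$trials$score)), 2L)
  expect_error(run_search(search_space(), 3,
                          objective = function(cfg) stop("no"), seed = 1),
               "no successful trials")
})

test_that("a two-trial training search on tiny phantoms produces a table", {
  ids <- c("a", "b", "c", "d", "e")
  data <- lapply(seq_along(ids), function(i)
    generate_phantom(phantom_spec(grid_shape = c(16, 16, 16), seed = i)))
  names(data) <- ids
  fold <- list(train = ids[1:4], validation = ids[5])
  sp <- search_space(inplane_spacing_mm = 1.0, window_xy = 16L,
                     window_z = 8L, batch_size = 1L,
                     architecture = "basic_unet")
  res <- run_search(sp, n_trials = 2, data_source = data, fold = fold,
                    seed = 3, depth = 1L, base_filters = 2L,
                    max_epochs = 2L, batches_per_epoch = 1L,
                    patience_epochs = 2L)
  expect_identical(nrow(res$trials), 2L)
  expect_true(all(is.finite(res$trials$score)))
  expect_equal(max(res$trials$score),
               res$trials$score[which.max(res$trials$score)])
})
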
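test_that("dice loss obeys its closed form, bounds, and symmetry", {
  # perfect one-hot prediction, both foreground classes present
  truth <- array(c(rep(0L, 20), rep(1L, 22), rep(2L, 22)), c(4, 4, 4))
  onehot <- array(0, c(4, 4, 4, 3))
  for (cl in 0:2) onehot[, , , cl + 1][truth == cl] <- 1
  expect_lte(dice_loss(onehot, truth), 1e-6)

  # all-background prediction against foreground truth: loss -> 1
  bg <- array(0, c(4, 4, 4, 3)); bg[, , , 1] <- 1
  expect_gt(dice_loss(bg, truth), 1 - 1e-4)

  # uniform probabilities match the direct formula to 1e-10
  N <- 64; eps <- 1e-6
  unif <- array(1 / 3, c(4, 4, 4, 3))
  n1 <- sum(truth == 1L); n2 <- sum(truth == 2L)
  closed <- 1 - (1 / 2) * ((2 * n1 / 3 + eps) / (N / 3 + n1 + eps) +
                             (2 * n2 / 3 + eps) / (N / 3 + n2 + eps))
  expect_lt(abs(dice_loss(unif, truth) - closed), 1e-10)

  # permutation invariance over voxels
  set.seed(1)
  probs <- array(runif(64 * 3), c(4, 4, 4, 3))
  pm <- focusedcta:::as_prob_matrix(probs); pm <- pm / rowSums(pm)
  perm <- sample(64)
  expect_equal(dice_loss(pm, as.vector(truth)),
               dice_loss(pm[perm, ], as.vector(truth)[perm]))

  # flipping one-hot predictions toward truth decreases the loss
  wrong <- array(0, c(4, 4, 4, 3)); wrong[, , , 1] <- 1
  wm <- matrix(wrong, 64, 3)
  tv <- as.vector(truth)
  prev <- dice_loss(wm, tv)
  for (v in which(tv != 0L)[1:10]) {
    wm[v, ] <- 0; wm[v, tv[v] + 1L] <- 1
    cur <- dice_loss(wm, tv)
    expect_lt(cur, prev)
    prev <- cur
  }
  expect_error(dice_loss(matrix(1 / 3, 10, 3), rep(0L, 9)), "shape")
})

test_that("fold plans are disjoint, complete, and reproducible", {
  ids <- sprintf("scan%03d", 1:100)
  plan <- make_folds(ids, fold_count = 5, validation_fraction = 0.1,
                     seed = 3)
  vals <- lapply(plan$folds, `[[`, "validation")
  expect_true(all(lengths(vals) == 10L))
  expect_identical(anyDuplicated(unlist(vals)), 0L)
  for (f in plan$folds) {
    expect_length(f$train, 90L)
    expect_setequal(c(f$train, f$validation), ids)
  }
  # scaled down: 10 ids, 5 folds, 10% validation -> singleton folds
  small <- make_folds(letters[1:10], 5, 0.1, seed = 2)
  expect_true(all(lengths(lapply(small$folds, `[[`, "validation")) == 1L))
  expect_identical(make_folds(ids, seed = 9), make_folds(ids, seed = 9))
  expect_error(make_folds(letters[1:3], 5), "at least")
})

test_that("early stopping retains the best epoch and stops on patience", {
  ids <- c("a", "b", "c")
  data <- lapply(ids, function(i)
    generate_phantom(phantom_spec(grid_shape = c(16, 16, 16),
                                  seed = match(i, ids))))
  names(data) <- ids
  fold <- list(train = c("a", "b"), validation = "c")
  arch <- tiny_arch()
  tcfg <- train_config(batch_size = 1, learning_rate = 1e-3,
                       optimizer = "adam", patience_epochs = 1L,
                       max_epochs = 10L, batches_per_epoch = 1L, seed = 1)
  # metric strictly worsens after epoch 1 -> stop at epoch 2, best = 1
  fit <- train_fold(fold, arch, tcfg, preproc_config(1.0, "z_norm"),
                    NULL, data,
                    metric_fn = function(net, val, epoch)
                      c(0.9, 0.9) - 0.1 * epoch)
  expect_identical(nrow(fit$history), 2L)
  expect_identical(fit$best_epoch, 1L)
  # the retained metric is never worse than any earlier epoch's
  expect_gte(fit$best_metric, max(fit$history$val_dice_mean))
  # log length equals epochs run
  fit2 <- train_fold(fold, arch, tcfg, preproc_config(1.0, "z_norm"),
                     NULL, data,
                     metric_fn = function(net, val, epoch)
                       c(0.5, 0.5) + 0.01 * epoch)
  expect_identical(nrow(fit2$history), 10L)
  expect_identical(fit2$best_epoch, 10L)
})

test_that("ensembles average member probabilities exactly", {
  # constant stubs: ensemble output is the element-wise mean
  m1 <- constant_model(c(0.2, 0.3, 0.5))
  m2 <- constant_model(c(0.6, 0.2, 0.2))
  ens <- structure(list(members = list(m1, m2)), class = "cta_ensemble")
  patch <- array(0, c(4, 4, 4))
  out <- predict_patch(ens, patch)
  expect_equal(out[1, 1, 1, ], c(0.4, 0.25, 0.35))

  # real networks: mean of independently saved outputs
  nets <- lapply(1:5, function(s) build_network(tiny_arch(), seed = s))
  patch <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  saved <- lapply(nets, predict_patch, patch = patch)
  manual <- Reduce(`+`, saved) / 5
  ens5 <- build_ensemble(nets)
  expect_lt(max(abs(predict_patch(ens5, patch) - manual)), 1e-12)

  # ensemble of one is the single model
  e1 <- build_ensemble(nets[1])
  expect_identical(predict_patch(e1, patch), saved[[1]])

  # mismatched configurations are rejected
  other <- build_network(arch_config("basic_unet", c(16, 16, 8),
                                     base_filters = 4, depth = 1))
  expect_error(build_ensemble(list(nets[[1]], other)), "mismatch")
})

test_that("optimizers reduce the dice loss on a fixed patch", {
  net <- build_network(tiny_arch(), seed = 6)
  set.seed(8)
  patch <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  truth <- array(0L, c(16, 16, 8))
  truth[5:12, 5:12, 3:6] <- 1L
  truth[1:3, 1:3, 1:2] <- 2L
  for (opt in c("adam", "rmsprop")) {
    n2 <- net
    st <- focusedcta:::opt_init(n2$params, opt)
    l0 <- NA
    for (i in 1:30) {
      fw <- focusedcta:::net_forward(n2, patch, keep_cache = TRUE)
      l <- dice_loss(fw$probs, truth)
      if (i == 1) l0 <- l
      g <- focusedcta:::net_backward(n2, fw$cache,
                                     focusedcta:::dice_loss_grad(fw$probs, truth))
      stp <- focusedcta:::opt_step(n2$params, g, st, opt, 3e-3)
      n2$params <- stp$params; st <- stp$state
    }
    lN <- dice_loss(focusedcta:::net_forward(n2, patch)$probs, truth)
    expect_lt(lN, l0 - 0.1)
  }
})
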
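#' Mean categorical Dice loss over the foreground classes
#'
#' Soft-Dice loss averaged over the two foreground classes (brain/cavity
#' and extracranial arteries):
#' `1 - (1/2) * sum_c (2 * sum_v p_cv g_cv + eps) / (sum_v p_cv + sum_v g_cv + eps)`
#' with `g` the one-hot truth and `eps` a smoothing constant. The loss lies
#' in `[0, 1]`, is 0 for a perfect one-hot prediction (when both foreground
#' classes are present), and is permutation-invariant over voxels.
#'
#' @param probs 4D array `(X, Y, Z, 3)` of class probabilities (or an
#'   `N x 3` matrix).
#' @param truth integer array/vector of matching voxel count, values in
#'   {0, 1, 2}.
#' @param eps smoothing constant, default `1e-6`.
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(probs, truth, eps = 1e-6) {
  pm <- as_prob_matrix(probs)
  tv <- as.integer(truth)
  if (nrow(pm) != length(tv)) stop("probs and truth shapes differ")
  s <- 0
  for (cl in 1:2) {
    g <- tv == cl
    p <- pm[, cl + 1L]
    s <- s + (2 * sum(p[g]) + eps) / (sum(p) + sum(g) + eps)
  }
  1 - s / 2
}

as_prob_matrix <- function(probs) {
  if (is.matrix(probs)) {
    if (ncol(probs) != 3L) stop("probability matrix must have 3 columns")
    return(probs)
  }
  d <- dim(probs)
  if (length(d) != 4L || d[4] != 3L)
    stop("probs must be an (X, Y, Z, 3) array or N x 3 matrix")
  matrix(probs, prod(d[1:3]), 3L)
}

# gradient of dice_loss wrt probabilities, same shape as probs
dice_loss_grad <- function(probs, truth, eps = 1e-6) {
  d <- dim(probs)
  pm <- as_prob_matrix(probs)
  tv <- as.integer(truth)
  g <- matrix(0, nrow(pm), 3L)
  for (cl in 1:2) {
    gv <- as.numeric(tv == cl)
    p <- pm[, cl + 1L]
    num <- 2 * sum(p * gv) + eps
    den <- sum(p) + sum(gv) + eps
    g[, cl + 1L] <- -(1 / 2) * (2 * gv * den - num) / den^2
  }
  if (length(d) == 4L) array(g, d) else g
}

#' Cross-validation fold plan
#'
#' Shuffles the scan ids and assigns each fold a disjoint validation set of
#' `validation_fraction` of the scans (default 10%); the remaining scans
#' form that fold's training set. With five folds and the default fraction,
#' half the scans serve as validators across folds — the 90/10 x 5
#' arithmetic of the training protocol.
#'
#' @param scan_ids character or integer vector of scan identifiers.
#' @param fold_count number of folds, default 5.
#' @param validation_fraction per-fold validation share, default 0.1; must
#'   satisfy `fold_count * validation_fraction <= 1`.
#' @param seed integer; the plan is deterministic given the seed.
#' @return An object of class `fold_plan`: per fold, `validation` and
#'   `train` id vectors.
#' @export
make_folds <- function(scan_ids, fold_count = 5L, validation_fraction = 0.1,
                       seed = 1L) {
  n <- length(scan_ids)
  fold_count <- as.integer(fold_count)
  if (n < fold_count) stop("need at least as many scans as folds")
  if (validation_fraction <= 0 || fold_count * validation_fraction > 1)
    stop("fold_count * validation_fraction must not exceed 1")
  nval <- max(1L, round(n * validation_fraction))
  if (nval * fold_count > n) stop("validation sets would overlap")
  perm <- with_seed(seed, sample(scan_ids))
  folds <- lapply(seq_len(fold_count), function(k) {
    val <- perm[(k - 1L) * nval + seq_len(nval)]
    list(validation = val, train = setdiff(scan_ids, val))
  })
  structure(list(folds = folds, scan_ids = scan_ids, seed = seed),
            class = "fold_plan")
}

#' Training configuration
#'
#' @param batch_size patches per optimization step, >= 1.
#' @param learning_rate optimizer step size, > 0.
#' @param optimizer `"rmsprop"` or `"adam"`.
#' @param patience_epochs early-stopping patience: training stops after
#'   this many epochs without validation improvement (default 50).
#' @param max_epochs hard epoch cap.
#' @param batches_per_epoch sampled batches that constitute one "epoch"
#'   (patch sampling has no natural epoch boundary).
#' @param seed integer RNG seed for sampling, augmentation, and weights.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 13L, learning_rate = 4e-4,
                         optimizer = c("rmsprop", "adam"),
                         patience_epochs = 50L, max_epochs = 1000L,
                         batches_per_epoch = 50L, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (patience_epochs < 1) stop("patience_epochs must be > 0")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 patience_epochs = as.integer(patience_epochs),
                 max_epochs = as.integer(max_epochs),
                 batches_per_epoch = as.integer(batches_per_epoch),
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---- nested-list parameter trees ---------------------------------------

tree_map <- function(x, f) {
  if (is.list(x)) lapply(x, tree_map, f = f) else f(x)
}

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    nms <- names(a)
    if (!is.null(nms) && !is.null(names(b))) {
      for (nm in nms) out[[nm]] <- tree_map2(a[[nm]], b[[nm]], f)
    } else {
      for (i in seq_along(a)) out[[i]] <- tree_map2(a[[i]], b[[i]], f)
    }
    out
  } else f(a, b)
}

# add L2 gradient 2*l2*W for every kernel leaf (names starting with "W")
add_l2_grads <- function(grads, params, l2) {
  if (l2 <= 0) return(grads)
  walk <- function(g, p) {
    if (!is.list(g)) return(g)
    for (nm in names(g)) {
      if (is.list(g[[nm]])) g[[nm]] <- walk(g[[nm]], p[[nm]])
      else if (startsWith(nm, "W")) g[[nm]] <- g[[nm]] + 2 * l2 * p[[nm]]
    }
    g
  }
  walk(grads, params)
}

opt_init <- function(params, optimizer) {
  z <- tree_map(params, function(x) x * 0)
  if (optimizer == "adam") list(m = z, v = z, t = 0L) else list(v = z)
}

opt_step <- function(params, grads, state, optimizer, lr) {
  if (optimizer == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    state$t <- state$t + 1L
    state$m <- tree_map2(state$m, grads, function(m, g) b1 * m + (1 - b1) * g)
    state$v <- tree_map2(state$v, grads, function(v, g) b2 * v + (1 - b2) * g^2)
    c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
    upd <- tree_map2(state$m, state$v,
                     function(m, v) (m / c1) / (sqrt(v / c2) + eps))
    params <- tree_map2(params, upd, function(p, u) p - lr * u)
  } else {  # rmsprop
    rho <- 0.9; eps <- 1e-7
    state$v <- tree_map2(state$v, grads,
                         function(v, g) rho * v + (1 - rho) * g^2)
    upd <- tree_map2(grads, state$v, function(g, v) g / (sqrt(v) + eps))
    params <- tree_map2(params, upd, function(p, u) p - lr * u)
  }
  list(params = params, state = state)
}

# resolve a data source (named list or function of id) to one scan
fetch_scan <- function(data_source, id) {
  sc <- if (is.function(data_source)) data_source(id)
  else data_source[[as.character(id)]]
  if (is.null(sc) || is.null(sc$volume) || is.null(sc$labels))
    stop("data source returned no volume/labels for scan ", id)
  sc
}

# preprocess one scan for training/inference under a preproc_config
preprocess_scan <- function(scan, preproc) {
  rs <- resample_inplane(scan$volume, preproc$inplane_spacing_mm,
                         scan$labels)
  nz <- normalize_volume(rs$volume, preproc$normalization)
  list(data = nz$data, stats = nz$stats,
       labels = if (!is.null(rs$labels)) rs$labels$labels)
}

# mean foreground dice of a model on preprocessed validation scans
validation_metric <- function(net, val_scans, window, overlap = 0) {
  per_class <- vapply(val_scans, function(sc) {
    probs <- sliding_window_predict(net, sc$data, window, overlap,
                                    pad_value = sc$stats$pad_value)
    pred <- labels_from_probabilities(probs)$labels
    c(dice_from_arrays(pred, sc$labels, 1L),
      dice_from_arrays(pred, sc$labels, 2L))
  }, c(0, 0))
  rowMeans(per_class)
}

#' Train one cross-validation fold
#'
#' Runs the patch-based training loop for a single fold: per epoch, a fixed
#' number of randomly sampled (and augmented) patch batches are optimized
#' against the categorical Dice loss; after each epoch the mean foreground
#' Dice over the full validation scans (sliding-window prediction) is
#' computed, the best-scoring weights are retained, and training stops
#' early once `patience_epochs` epochs pass without improvement.
#'
#' @param fold one entry of a [make_folds()] plan: list with `train` and
#'   `validation` id vectors.
#' @param arch an [arch_config()].
#' @param tcfg a [train_config()].
#' @param preproc a [preproc_config()].
#' @param augment an [augment_config()], or `NULL` for no augmentation.
#' @param data_source named list `id -> list(volume, labels)` or a function
#'   of the id returning the same.
#' @param reject_background re-draw all-background crops (default TRUE).
#' @param verbose print per-epoch progress.
#' @param metric_fn optional replacement for the validation metric, called
#'   as `metric_fn(net, val_scans, epoch)` and returning the per-class
#'   Dice vector `c(class1, class2)`; intended for diagnostics and tests.
#' @return An object of class `cta_segmenter`: the best network, the
#'   configurations, the per-epoch `history` (train loss, per-class and
#'   mean validation Dice), and `best_epoch`. Methods: `print`, `summary`,
#'   `predict`, `plot`.
#' @export
train_fold <- function(fold, arch, tcfg, preproc, augment = augment_config(),
                       data_source, reject_background = TRUE,
                       verbose = FALSE, metric_fn = NULL) {
  stopifnot(inherits(arch, "arch_config"), inherits(tcfg, "train_config"),
            inherits(preproc, "preproc_config"))
  train_scans <- lapply(fold$train, function(id)
    preprocess_scan(fetch_scan(data_source, id), preproc))
  val_scans <- lapply(fold$validation, function(id)
    preprocess_scan(fetch_scan(data_source, id), preproc))
  net <- build_network(arch, seed = tcfg$seed)
  state <- opt_init(net$params, tcfg$optimizer)
  window <- arch$window_shape
  best <- list(metric = -Inf, params = net$params, epoch = 0L)
  history <- NULL
  stall <- 0L
  with_seed(tcfg$seed + 1L, {
    for (epoch in seq_len(tcfg$max_epochs)) {
      ep_loss <- 0
      for (b in seq_len(tcfg$batches_per_epoch)) {
        gsum <- NULL
        closs <- 0
        for (s in seq_len(tcfg$batch_size)) {
          sc <- train_scans[[sample.int(length(train_scans), 1L)]]
          pp <- sample_patch(sc$data, sc$labels, window,
                             pad_value = sc$stats$pad_value,
                             reject_background = reject_background)
          if (!is.null(augment))
            pp <- augment_patch(pp, augment, pad_value = sc$stats$pad_value)
          fw <- net_forward(net, pp$image, keep_cache = TRUE)
          loss <- dice_loss(fw$probs, pp$labels)
          if (!is.finite(loss))
            stop("training diverged: non-finite loss at epoch ", epoch)
          closs <- closs + loss
          gp <- dice_loss_grad(fw$probs, pp$labels)
          g <- net_backward(net, fw$cache, gp)
          gsum <- if (is.null(gsum)) g else tree_map2(gsum, g, `+`)
        }
        g <- tree_map(gsum, function(x) x / tcfg$batch_size)
        g <- add_l2_grads(g, net$params, arch$l2_strength)
        st <- opt_step(net$params, g, state, tcfg$optimizer,
                       tcfg$learning_rate)
        net$params <- st$params
        state <- st$state
        ep_loss <- ep_loss + closs / tcfg$batch_size
      }
      vm <- if (is.null(metric_fn)) validation_metric(net, val_scans, window)
      else metric_fn(net, val_scans, epoch)
      metric <- mean(vm)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = ep_loss / tcfg$batches_per_epoch,
        val_dice_class1 = vm[1], val_dice_class2 = vm[2],
        val_dice_mean = metric))
      if (verbose)
        message(sprintf("epoch %d  loss %.4f  val dice %.3f/%.3f",
                        epoch, ep_loss / tcfg$batches_per_epoch,
                        vm[1], vm[2]))
      if (metric > best$metric) {
        best <- list(metric = metric, params = net$params, epoch = epoch,
                     per_class = vm)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= tcfg$patience_epochs) break
      }
    }
  })
  net$params <- best$params
  structure(
    list(network = net, arch = arch, train_config = tcfg, preproc = preproc,
         augment = augment, fold = fold, history = history,
         best_epoch = best$epoch, best_metric = best$metric,
         best_per_class = best$per_class),
    class = "cta_segmenter")
}

#' Averaging ensemble of per-fold models
#'
#' Combines fold models into an ensemble whose prediction is the
#' arithmetic mean of the members' per-voxel class probabilities (the mean
#' of normalized probability vectors needs no renormalization). Members
#' must share the architecture and preprocessing settings.
#'
#' @param members list of `cta_segmenter` (or `cta_network`) objects.
#' @return An object of class `cta_ensemble`.
#' @export
build_ensemble <- function(members) {
  if (length(members) < 1L) stop("ensemble needs at least one member")
  nets <- lapply(members, function(m)
    if (inherits(m, "cta_segmenter")) m$network else m)
  if (!all(vapply(nets, inherits, TRUE, "cta_network")))
    stop("members must be cta_segmenter or cta_network objects")
  ref <- nets[[1]]$cfg
  for (nt in nets[-1])
    if (!identical(nt$cfg, ref))
      stop("ensemble members have mismatched architecture configurations")
  pre <- if (inherits(members[[1]], "cta_segmenter")) members[[1]]$preproc
  if (inherits(members[[1]], "cta_segmenter")) {
    for (m in members[-1])
      if (inherits(m, "cta_segmenter") && !identical(m$preproc, pre))
        stop("ensemble members have mismatched preprocessing settings")
  }
  structure(list(members = nets, cfg = ref, preproc = pre,
                 sources = members),
            class = "cta_ensemble")
}

#' @export
predict_patch.cta_ensemble <- function(object, patch, ...) {
  acc <- NULL
  for (m in object$members) {
    p <- predict_patch(m, patch)
    acc <- if (is.null(acc)) p else acc + p
  }
  acc / length(object$members)
}

#' @export
predict_patch.cta_segmenter <- function(object, patch, ...) {
  predict_patch(object$network, patch)
}
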
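#' Hyperparameter search space
#'
#' The searched configuration space for the training pipeline: in-plane
#' spacing {0.5, 0.7, 1.0} mm; normalization {z_norm, divide_by_1000};
#' window X=Y in 160-256 (step 32) and Z in 16-64 (step 16); architecture
#' {basic, dual-attention}; batch size 1-15; learning rate and L2 in
#' [1e-4, 1e-3] (log-uniform); optimizer {adam, rmsprop}; instance norm
#' on/off; rotation and tilt frequencies in [0, 0.5]; noise frequency in
#' [0, 0.7]; noise factor in [1e-4, 1e-2] (log-uniform). Every domain can
#' be overridden (e.g. collapsed to a single point for reduced runs).
#'
#' @param ... named overrides of individual domains. Discrete domains are
#'   vectors of allowed values; continuous ones are `c(lo, hi)` ranges.
#' @return An object of class `search_space`.
#' @export
search_space <- function(...) {
  space <- list(
    inplane_spacing_mm = c(0.5, 0.7, 1.0),
    normalization = c("z_norm", "divide_by_1000"),
    window_xy = seq(160L, 256L, by = 32L),
    window_z = seq(16L, 64L, by = 16L),
    architecture = c("basic_unet", "dual_attention_unet"),
    batch_size = 1:15,
    learning_rate = c(1e-4, 1e-3),
    l2_strength = c(1e-4, 1e-3),
    optimizer = c("adam", "rmsprop"),
    instance_norm = c(TRUE, FALSE),
    rotation_freq = c(0, 0.5),
    tilt_freq = c(0, 0.5),
    noise_freq = c(0, 0.7),
    noise_factor = c(1e-4, 1e-2))
  over <- list(...)
  bad <- setdiff(names(over), names(space))
  if (length(bad)) stop("unknown search dimensions: ",
                        paste(bad, collapse = ", "))
  space[names(over)] <- over
  structure(space, class = "search_space")
}

#' The configuration found optimal by the original search
#'
#' Ships as the package's default full-scale configuration: 0.7 mm
#' in-plane spacing, z-normalization, 160 x 160 x 48 window,
#' dual-attention U-Net, batch 13, learning rate 4e-4, L2 2e-4, RMSProp,
#' instance normalization on, rotation/tilt/noise frequencies
#' 0.25/0.04/0.60, noise factor 0.003.
#'
#' @return A named list of hyperparameters (class `hyper_config`).
#' @export
default_hyperconfig <- function() {
  structure(list(
    inplane_spacing_mm = 0.7, normalization = "z_norm",
    window_xy = 160L, window_z = 48L,
    architecture = "dual_attention_unet", batch_size = 13L,
    learning_rate = 4e-4, l2_strength = 2e-4, optimizer = "rmsprop",
    instance_norm = TRUE, rotation_freq = 0.25, tilt_freq = 0.04,
    noise_freq = 0.60, noise_factor = 0.003),
    class = "hyper_config")
}

log_uniform <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))

#' Sample one configuration from the search space
#'
#' Discrete axes are sampled uniformly over their allowed values;
#' continuous rates/regularization axes (learning rate, L2, noise factor)
#' log-uniformly; other continuous axes uniformly.
#'
#' @param space a [search_space()].
#' @return A `hyper_config` inside the space's domains.
#' @export
sample_config <- function(space) {
  if (!inherits(space, "search_space")) stop("space must be a search_space")
  pick <- function(v) if (length(v) == 1L) v else v[sample.int(length(v), 1L)]
  cont <- function(v, log = FALSE) {
    if (length(v) == 1L) return(v)
    if (log) log_uniform(v[1], v[2]) else stats::runif(1, v[1], v[2])
  }
  structure(list(
    inplane_spacing_mm = pick(space$inplane_spacing_mm),
    normalization = pick(space$normalization),
    window_xy = pick(space$window_xy),
    window_z = pick(space$window_z),
    architecture = pick(space$architecture),
    batch_size = pick(space$batch_size),
    learning_rate = cont(space$learning_rate, log = TRUE),
    l2_strength = cont(space$l2_strength, log = TRUE),
    optimizer = pick(space$optimizer),
    instance_norm = pick(space$instance_norm),
    rotation_freq = cont(space$rotation_freq),
    tilt_freq = cont(space$tilt_freq),
    noise_freq = cont(space$noise_freq),
    noise_factor = cont(space$noise_factor, log = TRUE)),
    class = "hyper_config")
}

# expand a sampled hyper_config into the pipeline's config objects
hyperconfig_to_configs <- function(cfg, depth = 4L, base_filters = 16L,
                                   patience_epochs = 50L, max_epochs = 50L,
                                   batches_per_epoch = 50L, seed = 1L) {
  list(
    arch = arch_config(cfg$architecture,
                       c(cfg$window_xy, cfg$window_xy, cfg$window_z),
                       base_filters = base_filters, depth = depth,
                       instance_norm = cfg$instance_norm,
                       l2_strength = cfg$l2_strength),
    tcfg = train_config(cfg$batch_size, cfg$learning_rate, cfg$optimizer,
                        patience_epochs = patience_epochs,
                        max_epochs = max_epochs,
                        batches_per_epoch = batches_per_epoch, seed = seed),
    preproc = preproc_config(cfg$inplane_spacing_mm, cfg$normalization),
    augment = augment_config(cfg$rotation_freq, cfg$tilt_freq,
                             cfg$noise_freq, cfg$noise_factor))
}

#' Random hyperparameter search
#'
#' Draws `n_trials` configurations from the space and scores each with the
#' objective — by default, training a single cross-validation fold with a
#' capped epoch budget and reporting the best mean validation Dice. Failed
#' trials are recorded with an `NA` score and the search continues.
#'
#' @param space a [search_space()].
#' @param n_trials number of configurations to evaluate, >= 1.
#' @param objective `function(config) -> numeric score` (higher is
#'   better). When `NULL`, a training objective is built from
#'   `data_source` and `fold` (a [make_folds()] entry) with the reduced
#'   settings in `...` passed to `hyperconfig_to_configs()`.
#' @param data_source,fold used only by the default training objective.
#' @param seed integer; the sampled sequence is reproducible.
#' @param out_csv optional path; when given, the trial table is also
#'   written there as CSV.
#' @param ... forwarded to `hyperconfig_to_configs()`.
#' @return List with `trials` (data frame of sampled parameters and
#'   scores, one row per attempted trial) and `best` (the top-scoring
#'   `hyper_config`).
#' @export
run_search <- function(space, n_trials, objective = NULL,
                       data_source = NULL, fold = NULL, seed = 1L,
                       out_csv = NULL, ...) {
  if (n_trials < 1L) stop("n_trials must be >= 1")
  if (is.null(objective)) {
    if (is.null(data_source) || is.null(fold))
      stop("default objective needs data_source and fold")
    extra <- list(...)
    objective <- function(cfg) {
      cf <- do.call(hyperconfig_to_configs, c(list(cfg), extra))
      fit <- train_fold(fold, cf$arch, cf$tcfg, cf$preproc, cf$augment,
                        data_source)
      fit$best_metric
    }
  }
  configs <- with_seed(seed, lapply(seq_len(n_trials),
                                    function(i) sample_config(space)))
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    score <- tryCatch(objective(configs[[i]]),
                      error = function(e) NA_real_)
    rows[[i]] <- cbind(data.frame(trial = i, score = score),
                       as.data.frame(unclass(configs[[i]])))
  }
  trials <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(trials, out_csv,
                                          row.names = FALSE)
  if (all(is.na(trials$score))) stop("no successful trials")
  best <- configs[[which.max(trials$score)]]
  list(trials = trials, best = best)
}
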
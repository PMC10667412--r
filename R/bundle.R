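#' Save a fitted model as a versioned bundle directory
#'
#' Writes the network weights plus a JSON manifest recording the
#' architecture, preprocessing, training configuration, fold membership,
#' and training history, so a bundle is self-describing and reloadable.
#'
#' @param fit a `cta_segmenter`.
#' @param dir bundle directory (created).
#' @return `dir`, invisibly.
#' @export
save_model_bundle <- function(fit, dir) {
  if (!inherits(fit, "cta_segmenter")) stop("fit must be a cta_segmenter")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    format_version = 1L,
    architecture = unclass(fit$arch),
    preprocessing = unclass(fit$preproc),
    augmentation = if (!is.null(fit$augment)) unclass(fit$augment),
    training = unclass(fit$train_config),
    fold = fit$fold,
    best_epoch = fit$best_epoch,
    best_metric = fit$best_metric,
    history = fit$history)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(fit$network$params, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' Load a model bundle
#'
#' @param dir directory written by [save_model_bundle()].
#' @return A `cta_segmenter`.
#' @export
load_model_bundle <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  arch <- arch_config(mf$architecture$architecture,
                      mf$architecture$window_shape,
                      mf$architecture$base_filters, mf$architecture$depth,
                      mf$architecture$instance_norm,
                      mf$architecture$l2_strength)
  net <- structure(list(cfg = arch,
                        params = readRDS(file.path(dir, "weights.rds"))),
                   class = "cta_network")
  structure(
    list(network = net, arch = arch,
         train_config = do.call(train_config, mf$training[
           c("batch_size", "learning_rate", "optimizer", "patience_epochs",
             "max_epochs", "batches_per_epoch", "seed")]),
         preproc = preproc_config(mf$preprocessing$inplane_spacing_mm,
                                  mf$preprocessing$normalization),
         augment = if (!is.null(mf$augmentation))
           do.call(augment_config, mf$augmentation),
         fold = mf$fold, history = mf$history,
         best_epoch = mf$best_epoch, best_metric = mf$best_metric,
         best_per_class = c(NA_real_, NA_real_)),
    class = "cta_segmenter")
}

#' Read an experiment configuration from YAML
#'
#' Builds the four pipeline configuration objects from one experiment
#' file with optional sections `arch`, `train`, `preproc`, `augment`;
#' omitted fields take the package defaults (the full-scale optimum).
#'
#' @param path YAML file.
#' @return List with `arch`, `tcfg`, `preproc`, `augment`.
#' @export
read_experiment_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  call_with <- function(f, args) do.call(f, args[names(args) %in%
                                                  names(formals(f))])
  list(arch = call_with(arch_config, c(y$arch)),
       tcfg = call_with(train_config, c(y$train)),
       preproc = call_with(preproc_config, c(y$preproc)),
       augment = call_with(augment_config, c(y$augment)))
}
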
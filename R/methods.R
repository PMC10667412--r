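#' @export
print.cta_network <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("<cta_network> %s, window %s, base %d, depth %d, %s parameters\n",
              cfg$architecture,
              paste(cfg$window_shape, collapse = "x"),
              cfg$base_filters, cfg$depth,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @export
print.cta_segmenter <- function(x, ...) {
  cat("Focused-view CTA segmentation model\n")
  print(x$network)
  cat(sprintf("  trained %d epoch(s); best epoch %d, validation Dice %.3f (class 1 %.3f, class 2 %.3f)\n",
              nrow(x$history), x$best_epoch, x$best_metric,
              x$best_per_class[1], x$best_per_class[2]))
  invisible(x)
}

#' @export
summary.cta_segmenter <- function(object, ...) {
  out <- list(
    architecture = object$arch$architecture,
    window = object$arch$window_shape,
    parameters = n_parameters(object),
    epochs_run = nrow(object$history),
    best_epoch = object$best_epoch,
    best_validation_dice = object$best_metric,
    best_per_class = object$best_per_class,
    optimizer = object$train_config$optimizer,
    learning_rate = object$train_config$learning_rate,
    train_scans = length(object$fold$train),
    validation_scans = length(object$fold$validation))
  class(out) <- "summary.cta_segmenter"
  out
}

#' @export
print.summary.cta_segmenter <- function(x, ...) {
  cat(sprintf(
    "Architecture: %s (%s window, %s parameters)\n",
    x$architecture, paste(x$window, collapse = "x"),
    format(x$parameters, big.mark = ",")))
  cat(sprintf("Training: %d scans, %d validation; %s, lr %g\n",
              x$train_scans, x$validation_scans, x$optimizer,
              x$learning_rate))
  cat(sprintf(
    "Best epoch %d of %d: mean validation Dice %.3f (brain/cavity %.3f, arteries %.3f)\n",
    x$best_epoch, x$epochs_run, x$best_validation_dice,
    x$best_per_class[1], x$best_per_class[2]))
  invisible(x)
}

#' Segment a CTA volume with a trained model
#'
#' Runs the full inference pipeline — in-plane resampling, normalization,
#' sliding-window prediction with overlap averaging, and nearest-neighbour
#' mapping of the predicted labels back onto the native voxel grid.
#'
#' @param object a `cta_segmenter` (or `cta_ensemble`).
#' @param volume a [cta_volume()] in HU.
#' @param type `"labels"` (default) for a native-grid [cta_labelmap()],
#'   `"probs"` for the class-probability array on the resampled grid.
#' @param overlap sliding-window overlap fraction, default 0.5.
#' @param ... unused.
#' @return A [cta_labelmap()] or a probability array, per `type`.
#' @export
predict.cta_segmenter <- function(object, volume,
                                  type = c("labels", "probs"),
                                  overlap = 0.5, ...) {
  type <- match.arg(type)
  seg <- segment_volume(object, volume, overlap)
  if (type == "labels") seg$labels else seg$probs
}

#' @rdname predict.cta_segmenter
#' @export
predict.cta_ensemble <- function(object, volume,
                                 type = c("labels", "probs"),
                                 overlap = 0.5, ...) {
  type <- match.arg(type)
  seg <- segment_volume(object, volume, overlap)
  if (type == "labels") seg$labels else seg$probs
}

#' @export
print.cta_ensemble <- function(x, ...) {
  cat(sprintf("<cta_ensemble> %d member(s), %s, window %s\n",
              length(x$members), x$cfg$architecture,
              paste(x$cfg$window_shape, collapse = "x")))
  invisible(x)
}

#' Training-history curves
#'
#' Plots the per-epoch training loss and validation Dice of a fitted
#' segmentation model, marking the retained (best) epoch.
#'
#' @param x a `cta_segmenter`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cta_segmenter <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch,
                    cbind(h$train_loss, h$val_dice_class1,
                          h$val_dice_class2),
                    type = "l", lty = 1, lwd = 2,
                    col = c("grey40", "steelblue", "firebrick"),
                    xlab = "epoch", ylab = "value", ylim = c(0, 1), ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("right",
                   c("training Dice loss", "val Dice class 1",
                     "val Dice class 2", "best epoch"),
                   lty = c(1, 1, 1, 3), lwd = c(2, 2, 2, 1),
                   col = c("grey40", "steelblue", "firebrick", "black"),
                   bty = "n")
  invisible(x)
}
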
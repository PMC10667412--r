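#' Sliding-window full-volume prediction with overlap averaging
#'
#' Tiles a (normalized) volume with network-sized windows placed at stride
#' `window * (1 - overlap_fraction)` along each axis, the final window
#' snapped to the far edge, and averages the per-voxel class probabilities
#' over all windows covering each voxel (unweighted mean; the mean of
#' normalized probability vectors is itself normalized). Volumes smaller
#' than the window are padded with `pad_value` and the padding is cropped
#' from the output.
#'
#' @param object anything with a [predict_patch()] method (a
#'   `cta_network`, `cta_segmenter`, `cta_ensemble`, or a test stub).
#' @param data 3D array of normalized intensities.
#' @param window_shape integer length-3 window.
#' @param overlap_fraction fraction of window overlap in `[0, 1)`.
#' @param pad_value padding intensity for undersized volumes.
#' @return 4D array `(X, Y, Z, 3)` of averaged class probabilities on the
#'   input grid.
#' @export
sliding_window_predict <- function(object, data, window_shape,
                                   overlap_fraction = 0.5,
                                   pad_value = -1) {
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must lie in [0, 1)")
  window_shape <- as.integer(window_shape)
  orig <- dim(data)
  data <- pad_to_window(data, window_shape, pad_value)
  d <- dim(data)
  if (any(window_shape > d)) stop("window larger than padded volume")
  starts <- lapply(1:3, function(a) {
    stride <- max(1L, as.integer(round(window_shape[a] *
                                         (1 - overlap_fraction))))
    s <- seq.int(1L, max(1L, d[a] - window_shape[a] + 1L), by = stride)
    last <- d[a] - window_shape[a] + 1L
    if (s[length(s)] != last) s <- c(s, last)  # snap to the far edge
    unique(s)
  })
  acc <- array(0, c(d, 3L))
  cnt <- array(0, d)
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    ix <- sx + seq_len(window_shape[1]) - 1L
    iy <- sy + seq_len(window_shape[2]) - 1L
    iz <- sz + seq_len(window_shape[3]) - 1L
    p <- predict_patch(object, data[ix, iy, iz, drop = FALSE])
    acc[ix, iy, iz, ] <- acc[ix, iy, iz, , drop = FALSE] + p
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  probs <- acc / as.vector(cnt)
  probs[seq_len(orig[1]), seq_len(orig[2]), seq_len(orig[3]), ,
        drop = FALSE]
}

#' Discrete labels from a probability map
#'
#' Per-voxel argmax over the class axis; ties break toward the lowest
#' class index (a uniform map is therefore all background).
#'
#' @param probs 4D array `(X, Y, Z, 3)` of class probabilities.
#' @param spacing,origin geometry for the returned label map.
#' @return A [cta_labelmap()].
#' @export
labels_from_probabilities <- function(probs, spacing = c(1, 1, 1),
                                      origin = c(0, 0, 0)) {
  d <- dim(probs)
  if (length(d) != 4L || d[4] != 3L)
    stop("probs must be an (X, Y, Z, 3) array")
  pm <- matrix(probs, prod(d[1:3]), 3L)
  lab <- max.col(pm, ties.method = "first") - 1L
  cta_labelmap(array(lab, d[1:3]), spacing = spacing, origin = origin)
}
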
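# Shared in-code fixtures: small phantoms, reduced networks, stub models.

small_phantom_spec <- function(seed = 1L, ...) {
  phantom_spec(grid_shape = c(48, 48, 48), spacing_mm = c(1, 1, 1),
               seed = seed, ...)
}

tiny_arch <- function(architecture = "basic_unet") {
  arch_config(architecture, window_shape = c(16, 16, 8),
              base_filters = 2, depth = 1)
}

reduced_arch <- function(architecture = "dual_attention_unet") {
  arch_config(architecture, window_shape = c(32, 32, 16),
              base_filters = 8, depth = 2)
}

# model stub emitting a fixed probability vector at every voxel
constant_model <- function(p) {
  structure(list(p = p / sum(p)), class = "constant_model")
}

predict_patch.constant_model <- function(object, patch, ...) {
  d <- dim(patch)[1:3]
  array(rep(object$p, each = prod(d)), c(d, 3L))
}

# stub whose output depends on the input patch (for translation tests):
# class-1 probability follows the voxel intensity through a logistic
intensity_model <- function() structure(list(), class = "intensity_model")

predict_patch.intensity_model <- function(object, patch, ...) {
  d <- dim(patch)[1:3]
  p1 <- 1 / (1 + exp(-as.vector(patch)))
  array(c(1 - p1, p1, numeric(length(p1))), c(d, 3L))
}

# independent brute-force sliding window: explicit per-voxel sum/count
# accumulation written without reference to the package implementation
brute_force_sliding <- function(model, data, window, overlap) {
  d <- dim(data)
  acc <- array(0, c(d, 3L))
  cnt <- array(0L, d)
  axis_starts <- function(n, w) {
    stride <- max(1L, as.integer(round(w * (1 - overlap))))
    s <- integer(0)
    pos <- 1L
    while (pos + w - 1L <= n) {
      s <- c(s, pos)
      pos <- pos + stride
    }
    if (s[length(s)] + w - 1L < n) s <- c(s, n - w + 1L)
    s
  }
  sx <- axis_starts(d[1], window[1])
  sy <- axis_starts(d[2], window[2])
  sz <- axis_starts(d[3], window[3])
  for (a in sx) for (b in sy) for (cc in sz) {
    ii <- a:(a + window[1] - 1L)
    jj <- b:(b + window[2] - 1L)
    kk <- cc:(cc + window[3] - 1L)
    p <- predict_patch(model, data[ii, jj, kk, drop = FALSE])
    for (cl in 1:3)
      acc[ii, jj, kk, cl] <- acc[ii, jj, kk, cl] + p[, , , cl]
    cnt[ii, jj, kk] <- cnt[ii, jj, kk] + 1L
  }
  for (cl in 1:3) acc[, , , cl] <- acc[, , , cl] / cnt
  acc
}

registerS3method("predict_patch", "constant_model", predict_patch.constant_model,
                 envir = asNamespace("focusedcta"))
registerS3method("predict_patch", "intensity_model", predict_patch.intensity_model,
                 envir = asNamespace("focusedcta"))
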
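#' Segmentation network configuration
#'
#' Describes a 3-class patch-segmentation network: either a basic 3D U-Net
#' or the dual-attention variant, which adds parallel position-attention
#' (spatial affinity over the flattened bottleneck voxels) and
#' channel-attention blocks at the bottleneck, their outputs summed into
#' the bottleneck features. Both attention gates are scaled by coefficients
#' learned from zero, so an untrained dual-attention network starts from
#' the basic U-Net function.
#'
#' @param architecture `"basic_unet"` or `"dual_attention_unet"`.
#' @param window_shape integer length-3 patch shape (X, Y, Z); each axis
#'   must be divisible by `2^depth`.
#' @param base_filters channel count at the first encoder level; doubled at
#'   each deeper level.
#' @param depth number of pooling steps (default 4 at full scale; 2 is the
#'   reduced desk-scale setting used throughout the tests).
#' @param instance_norm logical, apply instance normalization after every
#'   convolution.
#' @param l2_strength L2 kernel-regularization coefficient, >= 0.
#' @return An object of class `arch_config`.
#' @export
arch_config <- function(architecture = c("dual_attention_unet", "basic_unet"),
                        window_shape = c(160, 160, 48),
                        base_filters = 16, depth = 4,
                        instance_norm = TRUE, l2_strength = 2e-4) {
  architecture <- match.arg(architecture)
  window_shape <- as.integer(window_shape)
  if (length(window_shape) != 3L || any(window_shape < 4L))
    stop("window_shape must be three integers >= 4")
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  if (any(window_shape %% (2L^depth) != 0L))
    stop("window_shape must be divisible by 2^depth on every axis")
  if (l2_strength < 0) stop("l2_strength must be >= 0")
  structure(
    list(architecture = architecture, window_shape = window_shape,
         base_filters = as.integer(base_filters), depth = depth,
         instance_norm = isTRUE(instance_norm), l2_strength = l2_strength,
         class_count = 3L),
    class = "arch_config")
}

he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

new_conv <- function(cin, cout, instance_norm) {
  p <- list(W = he_init(27L * cin, cout), b = numeric(cout))
  if (instance_norm) {
    p$gamma <- rep(1, cout)
    p$beta <- numeric(cout)
  }
  p
}

#' Build a segmentation network
#'
#' Instantiates the network described by an [arch_config()] with
#' He-initialized weights. The result maps an image patch of the configured
#' window shape to a per-voxel probability map over the three classes
#' (background, brain/cavity, extracranial arteries), probabilities summing
#' to one at every voxel.
#'
#' @param cfg an [arch_config()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `cta_network`; `predict_patch()` runs a
#'   forward pass, `n_parameters()` reports the trainable parameter count.
#' @examples
#' net <- build_network(arch_config("basic_unet", c(16, 16, 8),
#'                                  base_filters = 4, depth = 1))
#' p <- predict_patch(net, array(0, c(16, 16, 8)))
#' range(apply(p, 1:3, sum))  # 1 at every voxel
#' @export
build_network <- function(cfg, seed = 1L) {
  if (!inherits(cfg, "arch_config")) stop("cfg must be an arch_config")
  d <- cfg$depth; f <- cfg$base_filters; inn <- cfg$instance_norm
  with_seed(seed, {
    params <- list(enc = vector("list", d), dec = vector("list", d))
    cin <- 1L
    for (l in seq_len(d)) {
      cl <- f * 2L^(l - 1L)
      params$enc[[l]] <- list(a = new_conv(cin, cl, inn),
                              b = new_conv(cl, cl, inn))
      cin <- cl
    }
    cb <- f * 2L^d
    params$bottleneck <- list(a = new_conv(cin, cb, inn),
                              b = new_conv(cb, cb, inn))
    if (cfg$architecture == "dual_attention_unet") {
      cq <- max(1L, cb %/% 8L)
      params$attn <- list(
        Wq = he_init(cb, cq), Wk = he_init(cb, cq), Wv = he_init(cb, cb),
        gamma = 0, beta = 0)
    }
    cup <- cb
    for (l in rev(seq_len(d))) {
      cl <- f * 2L^(l - 1L)
      params$dec[[l]] <- list(
        up = list(W = he_init(cup, cl), b = numeric(cl)),  # 1x1 up-conv
        a = new_conv(2L * cl, cl, inn),
        b = new_conv(cl, cl, inn))
      cup <- cl
    }
    params$head <- list(W = he_init(f, cfg$class_count),
                        b = numeric(cfg$class_count))
    structure(list(cfg = cfg, params = params), class = "cta_network")
  })
}

#' Trainable parameter count
#' @param object a `cta_network`, `cta_segmenter`, or `cta_ensemble`.
#' @return Integer number of trainable scalars.
#' @export
n_parameters <- function(object) {
  if (inherits(object, "cta_segmenter")) object <- object$network
  if (inherits(object, "cta_ensemble"))
    return(sum(vapply(object$members, n_parameters, 0)))
  sum(unlist(rapply(object$params, length, how = "unlist")))
}

conv_block_fwd <- function(x, p, inn) {
  cv <- conv3_fwd(x, p$W, p$b)
  if (inn) {
    nm <- inorm_fwd(cv$y, p$gamma, p$beta)
    rl <- relu_fwd(nm$y)
    list(y = rl$y, conv = cv, norm = nm, relu = rl)
  } else {
    rl <- relu_fwd(cv$y)
    list(y = rl$y, conv = cv, relu = rl)
  }
}

conv_block_bwd <- function(cache, p, inn, gy) {
  gy <- relu_bwd(cache$relu, gy)
  g <- list()
  if (inn) {
    nb <- inorm_bwd(cache$norm, p$gamma, gy)
    g$gamma <- nb$ggamma; g$beta <- nb$gbeta
    gy <- nb$gx
  }
  cb <- conv3_bwd(cache$conv, p$W, gy)
  g$W <- cb$gW; g$b <- cb$gb
  list(gx = cb$gx, grads = g)
}

# Full forward pass; keep_cache = TRUE retains every intermediate needed by
# net_backward (training); FALSE frees them (inference).
net_forward <- function(net, patch, keep_cache = FALSE) {
  cfg <- net$cfg; P <- net$params
  if (length(dim(patch)) == 3L) dim(patch) <- c(dim(patch), 1L)
  stopifnot(all(dim(patch)[1:3] == cfg$window_shape))
  inn <- cfg$instance_norm; d <- cfg$depth
  cache <- list(enc = vector("list", d), pool = vector("list", d),
                dec = vector("list", d))
  x <- patch
  skips <- vector("list", d)
  for (l in seq_len(d)) {
    ba <- conv_block_fwd(x, P$enc[[l]]$a, inn)
    bb <- conv_block_fwd(ba$y, P$enc[[l]]$b, inn)
    skips[[l]] <- bb$y
    pl <- maxpool2_fwd(bb$y)
    x <- pl$y
    if (keep_cache) {
      cache$enc[[l]] <- list(a = ba, b = bb)
      cache$pool[[l]] <- pl[c("arg", "in_dims")]
    }
  }
  ba <- conv_block_fwd(x, P$bottleneck$a, inn)
  bb <- conv_block_fwd(ba$y, P$bottleneck$b, inn)
  x <- bb$y
  if (keep_cache) cache$bottleneck <- list(a = ba, b = bb)
  if (cfg$architecture == "dual_attention_unet") {
    db <- dim(x)
    Fm <- matrix(x, prod(db[1:3]), db[4])
    pa <- posattn_fwd(Fm, P$attn)
    ca <- chanattn_fwd(Fm, P$attn)
    x <- array(pa$y + ca$y - Fm, db)  # F + gamma*PA + beta*CA
    if (keep_cache) cache$attn <- list(pa = pa, ca = ca, Fm = Fm, dims = db)
  }
  for (l in rev(seq_len(d))) {
    up <- upsample2_fwd(x)
    uc <- conv1_fwd(up, P$dec[[l]]$up$W, P$dec[[l]]$up$b)
    ur <- relu_fwd(uc$y)
    cat_in <- abind4(ur$y, skips[[l]])
    ba <- conv_block_fwd(cat_in, P$dec[[l]]$a, inn)
    bb <- conv_block_fwd(ba$y, P$dec[[l]]$b, inn)
    x <- bb$y
    if (keep_cache)
      cache$dec[[l]] <- list(up = uc, urelu = ur, a = ba, b = bb,
                             up_ch = dim(ur$y)[4])
  }
  hd <- conv1_fwd(x, P$head$W, P$head$b)
  probs <- softmax_fwd(hd$y)
  if (keep_cache) {
    cache$head <- hd
    cache$probs <- probs
  }
  list(probs = probs, cache = if (keep_cache) cache else NULL)
}

# concatenate two (X,Y,Z,C) arrays along channels
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# Backward pass from d(loss)/d(probs); returns gradients mirroring params.
net_backward <- function(net, cache, gprobs) {
  cfg <- net$cfg; P <- net$params; inn <- cfg$instance_norm; d <- cfg$depth
  G <- list(enc = vector("list", d), dec = vector("list", d))
  gz <- softmax_bwd(cache$probs, gprobs)
  hb <- conv1_bwd(cache$head, P$head$W, gz)
  G$head <- list(W = hb$gW, b = hb$gb)
  gx <- hb$gx
  gskips <- vector("list", d)
  for (l in seq_len(d)) {
    bb <- conv_block_bwd(cache$dec[[l]]$b, P$dec[[l]]$b, inn, gx)
    ba <- conv_block_bwd(cache$dec[[l]]$a, P$dec[[l]]$a, inn, bb$gx)
    gcat <- ba$gx
    nup <- cache$dec[[l]]$up_ch
    gskips[[l]] <- gcat[, , , nup + seq_len(dim(gcat)[4] - nup), drop = FALSE]
    gup <- relu_bwd(cache$dec[[l]]$urelu,
                    gcat[, , , seq_len(nup), drop = FALSE])
    ub <- conv1_bwd(cache$dec[[l]]$up, P$dec[[l]]$up$W, gup)
    G$dec[[l]] <- list(up = list(W = ub$gW, b = ub$gb),
                       a = ba$grads, b = bb$grads)
    gx <- upsample2_bwd(ub$gx)
  }
  if (cfg$architecture == "dual_attention_unet") {
    at <- cache$attn
    gym <- matrix(gx, prod(at$dims[1:3]), at$dims[4])
    pb <- posattn_bwd(at$pa, at$Fm, P$attn, gym)
    cb <- chanattn_bwd(at$ca, at$Fm, P$attn, gym)
    G$attn <- c(pb$grads, cb$grads)
    gx <- array(pb$gF + cb$gF - gym, at$dims)  # direct path counted once
  }
  bb <- conv_block_bwd(cache$bottleneck$b, P$bottleneck$b, inn, gx)
  ba <- conv_block_bwd(cache$bottleneck$a, P$bottleneck$a, inn, bb$gx)
  G$bottleneck <- list(a = ba$grads, b = bb$grads)
  gx <- ba$gx
  for (l in rev(seq_len(d))) {
    gpool <- maxpool2_bwd(cache$pool[[l]], gx)
    gpool <- gpool + gskips[[l]]
    bb <- conv_block_bwd(cache$enc[[l]]$b, P$enc[[l]]$b, inn, gpool)
    ba <- conv_block_bwd(cache$enc[[l]]$a, P$enc[[l]]$a, inn, bb$gx)
    G$enc[[l]] <- list(a = ba$grads, b = bb$grads)
    gx <- ba$gx
  }
  G
}

#' Per-voxel class probabilities for one patch
#'
#' Runs a forward pass of a network (or averages an ensemble's members) on
#' a single image patch in normalized intensity units.
#'
#' @param object a `cta_network`, `cta_segmenter`, or `cta_ensemble`.
#' @param patch array of the configured window shape.
#' @param ... unused.
#' @return Array `window_shape x 3` of class probabilities.
#' @export
predict_patch <- function(object, patch, ...) UseMethod("predict_patch")

#' @export
predict_patch.cta_network <- function(object, patch, ...) {
  net_forward(object, patch, keep_cache = FALSE)$probs
}
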
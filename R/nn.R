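# Low-level differentiable 3D layers.
#
# All layers operate on a single sample laid out as (X, Y, Z, C) arrays.
# Convolutions use im2col: the 3x3x3 neighbourhood of every voxel is
# gathered into an N x 27C matrix (N = X*Y*Z) so the convolution itself is
# one BLAS matrix product. Backward passes are hand-derived; gradient
# correctness is checked against central finite differences in the tests.

# ---- im2col / col2im for a 3x3x3 kernel, zero ("same") padding ----------
# (compiled kernels in src/conv3.cpp; pure data movement, matmul is BLAS)

im2col3 <- function(x) im2col3_cpp(x, dim(x))

col2im3 <- function(gcols, dims) col2im3_cpp(gcols, as.integer(dims))

# ---- convolutions -------------------------------------------------------

conv3_fwd <- function(x, W, b) {
  d <- dim(x)
  cols <- im2col3(x)
  y <- cols %*% W
  y <- sweep(y, 2L, b, "+")
  list(y = array(y, c(d[1:3], ncol(W))), cols = cols, in_dims = d)
}

conv3_bwd <- function(cache, W, gy) {
  d <- dim(gy)
  gym <- matrix(gy, prod(d[1:3]), d[4])
  gW <- crossprod(cache$cols, gym)
  gb <- colSums(gym)
  gx <- col2im3(tcrossprod(gym, W), cache$in_dims)
  list(gx = gx, gW = gW, gb = gb)
}

conv1_fwd <- function(x, W, b) {
  d <- dim(x)
  xm <- matrix(x, prod(d[1:3]), d[4])
  y <- sweep(xm %*% W, 2L, b, "+")
  list(y = array(y, c(d[1:3], ncol(W))), xm = xm, in_dims = d)
}

conv1_bwd <- function(cache, W, gy) {
  d <- dim(gy)
  gym <- matrix(gy, prod(d[1:3]), d[4])
  list(gx = array(tcrossprod(gym, W), cache$in_dims),
       gW = crossprod(cache$xm, gym), gb = colSums(gym))
}

# ---- instance normalization (per-channel, per-sample) -------------------

inorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); N <- prod(d[1:3]); C <- d[4]
  xm <- matrix(x, N, C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  v <- colMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv, "*")
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(y = array(y, d), xhat = xhat, inv = inv, dims = d)
}

inorm_bwd <- function(cache, gamma, gy) {
  d <- cache$dims; N <- prod(d[1:3]); C <- d[4]
  gym <- matrix(gy, N, C)
  ggamma <- colSums(gym * cache$xhat)
  gbeta <- colSums(gym)
  gxhat <- sweep(gym, 2L, gamma, "*")
  m1 <- colMeans(gxhat)
  m2 <- colMeans(gxhat * cache$xhat)
  gx <- sweep(gxhat, 2L, m1) - sweep(cache$xhat, 2L, m2, "*")
  gx <- sweep(gx, 2L, cache$inv, "*")
  list(gx = array(gx, d), ggamma = ggamma, gbeta = gbeta)
}

# ---- ReLU ---------------------------------------------------------------

relu_fwd <- function(x) {
  m <- x > 0
  x[!m] <- 0
  list(y = x, mask = m)
}

relu_bwd <- function(cache, gy) {
  gy[!cache$mask] <- 0
  gy
}

# ---- 2x2x2 max pooling and nearest-neighbour upsampling -----------------

pool_candidates <- function(x) {
  d <- dim(x)
  lapply(seq_len(8L), function(o) {
    i <- (o - 1L) %% 2L; j <- ((o - 1L) %/% 2L) %% 2L; k <- (o - 1L) %/% 4L
    x[seq(1L + i, d[1], by = 2L), seq(1L + j, d[2], by = 2L),
      seq(1L + k, d[3], by = 2L), , drop = FALSE]
  })
}

maxpool2_fwd <- function(x) {
  cand <- pool_candidates(x)
  y <- cand[[1L]]
  arg <- array(1L, dim(y))
  for (o in 2:8) {
    m <- cand[[o]] > y
    y[m] <- cand[[o]][m]
    arg[m] <- o
  }
  list(y = y, arg = arg, in_dims = dim(x))
}

maxpool2_bwd <- function(cache, gy) {
  d <- cache$in_dims
  gx <- array(0, d)
  for (o in seq_len(8L)) {
    m <- cache$arg == o
    if (!any(m)) next
    i <- (o - 1L) %% 2L; j <- ((o - 1L) %/% 2L) %% 2L; k <- (o - 1L) %/% 4L
    sub <- array(0, dim(gy))
    sub[m] <- gy[m]
    gx[seq(1L + i, d[1], by = 2L), seq(1L + j, d[2], by = 2L),
       seq(1L + k, d[3], by = 2L), ] <- sub
  }
  gx
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L),
    rep(seq_len(d[3]), each = 2L), , drop = FALSE]
}

upsample2_bwd <- function(gy) {
  d <- dim(gy)
  out <- NULL
  for (o in seq_len(8L)) {
    i <- (o - 1L) %% 2L; j <- ((o - 1L) %/% 2L) %% 2L; k <- (o - 1L) %/% 4L
    sub <- gy[seq(1L + i, d[1], by = 2L), seq(1L + j, d[2], by = 2L),
              seq(1L + k, d[3], by = 2L), , drop = FALSE]
    out <- if (is.null(out)) sub else out + sub
  }
  out
}

# ---- softmax over the class axis ----------------------------------------

softmax_fwd <- function(z) {
  d <- dim(z)
  zm <- matrix(z, prod(d[1:3]), d[4])
  m <- zm[, 1L]
  for (j in 2:ncol(zm)) m <- pmax(m, zm[, j])
  e <- exp(zm - m)
  p <- e / rowSums(e)
  array(p, d)
}

# gradient through softmax: gz = p * (gp - sum_c gp * p)
softmax_bwd <- function(p, gp) {
  d <- dim(p)
  pm <- matrix(p, prod(d[1:3]), d[4])
  gm <- matrix(gp, prod(d[1:3]), d[4])
  s <- rowSums(gm * pm)
  array(pm * (gm - s), d)
}

# ---- dual attention (position + channel), transformer-scaled ------------

row_softmax <- function(E) {
  E <- E - apply(E, 1L, max)
  e <- exp(E)
  e / rowSums(e)
}

row_softmax_bwd <- function(A, gA) {
  A * (gA - rowSums(gA * A))
}

# Position attention: spatial affinity over the flattened bottleneck voxels.
# F is N x C; Q = F Wq, K = F Wk (C -> C/8), V = F Wv; A = softmax(QK'/s);
# out = F + gamma * A V, gamma learned from 0.
posattn_fwd <- function(Fm, p) {
  Q <- Fm %*% p$Wq; K <- Fm %*% p$Wk; V <- Fm %*% p$Wv
  s <- 1 / sqrt(ncol(Q))
  A <- row_softmax(tcrossprod(Q, K) * s)
  O <- A %*% V
  list(y = Fm + p$gamma * O, Q = Q, K = K, V = V, A = A, O = O, s = s)
}

posattn_bwd <- function(cache, Fm, p, gy) {
  gO <- p$gamma * gy
  ggamma <- sum(gy * cache$O)
  gA <- tcrossprod(gO, cache$V)
  gV <- crossprod(cache$A, gO)
  gE <- row_softmax_bwd(cache$A, gA) * cache$s
  gQ <- gE %*% cache$K
  gK <- crossprod(gE, cache$Q)
  gF <- gy + tcrossprod(gQ, p$Wq) + tcrossprod(gK, p$Wk) +
    tcrossprod(gV, p$Wv)
  list(gF = gF,
       grads = list(Wq = crossprod(Fm, gQ), Wk = crossprod(Fm, gK),
                    Wv = crossprod(Fm, gV), gamma = ggamma))
}

# Channel attention: affinity between channels; A = softmax(F'F/s) (C x C),
# out = F + beta * F A', beta learned from 0.
chanattn_fwd <- function(Fm, p) {
  s <- 1 / sqrt(nrow(Fm))
  E <- crossprod(Fm) * s
  A <- row_softmax(E)
  O <- tcrossprod(Fm, A)
  list(y = Fm + p$beta * O, A = A, O = O, s = s)
}

chanattn_bwd <- function(cache, Fm, p, gy) {
  gO <- p$beta * gy
  gbeta <- sum(gy * cache$O)
  gA <- crossprod(gO, Fm)
  gE <- row_softmax_bwd(cache$A, gA) * cache$s
  gF <- gy + gO %*% cache$A + Fm %*% (gE + t(gE))
  list(gF = gF, grads = list(beta = gbeta))
}
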
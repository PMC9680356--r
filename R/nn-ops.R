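# Low-level differentiable operations.
#
# Tensors are base-R numeric arrays with dim (C, H, W, N): channels first,
# then spatial rows/columns, then batch. Channel-first layout makes
# per-channel broadcasting a native column-major recycle and convolution a
# sum of per-offset GEMMs on free reshapes. Classifier-level quantities
# (logits, pooled features) are (N, C) matrices. Every op has a *_fwd
# returning list(out, cache) and a *_bwd returning the input gradient plus
# parameter gradients; the network-level code assembles these by hand (there
# is no autograd).

# ---- convolution: per-offset GEMM over a padded input -----------------------
#
# Weights are stored as a (k*k*in_c, out_c) matrix whose rows are ordered
# channel-fastest within each kernel offset (ki, kj), offset index
# (kj-1)*k + ki.

conv_init <- function(k, in_c, out_c, zero = FALSE) {
  fan_in <- k * k * in_c
  W <- if (zero) matrix(0, fan_in, out_c)
  else matrix(rnorm(fan_in * out_c, sd = sqrt(2 / fan_in)), fan_in, out_c)
  list(W = W, k = k, stride = 1L, pad = (k - 1L) %/% 2L)
}

pad_input <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2 * pad, d[3] + 2 * pad, d[4]))
  xp[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  xp
}

conv_fwd <- function(x, p, stride = p$stride) {
  d <- dim(x)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  k <- p$k; pad <- p$pad
  if (k == 1L) {
    # 1x1 convolution: a single GEMM (with column subsetting when strided)
    oh <- (H - 1L) %/% stride + 1L
    ow <- (W - 1L) %/% stride + 1L
    xs <- if (stride > 1L)
      x[, seq.int(1L, by = stride, length.out = oh),
        seq.int(1L, by = stride, length.out = ow), , drop = FALSE]
    else x
    M <- oh * ow * N
    dim(xs) <- c(C, M)
    Y <- crossprod(p$W, xs)
    dim(Y) <- c(ncol(p$W), oh, ow, N)
    return(list(out = Y,
                cache = list(slices = list(xs), in_dim = d, k = k,
                             stride = stride, pad = 0L, oh = oh, ow = ow,
                             W = p$W)))
  }
  xp <- pad_input(x, pad)
  oh <- (H + 2 * pad - k) %/% stride + 1L
  ow <- (W + 2 * pad - k) %/% stride + 1L
  M <- oh * ow * N
  out_c <- ncol(p$W)
  Y <- matrix(0, out_c, M)
  slices <- vector("list", k * k)
  off <- 0L
  si <- 0L
  for (kj in seq_len(k)) {
    cls <- seq.int(kj, by = stride, length.out = ow)
    for (ki in seq_len(k)) {
      rows <- seq.int(ki, by = stride, length.out = oh)
      sl <- xp[, rows, cls, , drop = FALSE]
      dim(sl) <- c(C, M)
      si <- si + 1L
      slices[[si]] <- sl
      Y <- Y + crossprod(p$W[off + seq_len(C), , drop = FALSE], sl)
      off <- off + C
    }
  }
  dim(Y) <- c(out_c, oh, ow, N)
  list(out = Y,
       cache = list(slices = slices, in_dim = d, k = k, stride = stride,
                    pad = pad, oh = oh, ow = ow, W = p$W))
}

conv_bwd <- function(dy, cache) {
  ca <- cache
  C <- ca$in_dim[1]; N <- ca$in_dim[4]
  oh <- ca$oh; ow <- ca$ow
  M <- oh * ow * N
  dY <- dy
  dim(dY) <- c(ncol(ca$W), M)
  if (ca$k == 1L) {
    dW <- tcrossprod(ca$slices[[1]], dY)
    dsl <- ca$W %*% dY
    if (ca$stride == 1L) {
      dim(dsl) <- ca$in_dim
      return(list(dx = dsl, grads = list(W = dW)))
    }
    dx <- array(0, ca$in_dim)
    dim(dsl) <- c(C, oh, ow, N)
    dx[, seq.int(1L, by = ca$stride, length.out = oh),
       seq.int(1L, by = ca$stride, length.out = ow), ] <- dsl
    return(list(dx = dx, grads = list(W = dW)))
  }
  dW <- matrix(0, nrow(ca$W), ncol(ca$W))
  dxp <- array(0, c(C, ca$in_dim[2] + 2 * ca$pad, ca$in_dim[3] + 2 * ca$pad, N))
  off <- 0L
  si <- 0L
  for (kj in seq_len(ca$k)) {
    cls <- seq.int(kj, by = ca$stride, length.out = ow)
    for (ki in seq_len(ca$k)) {
      rows <- seq.int(ki, by = ca$stride, length.out = oh)
      si <- si + 1L
      dW[off + seq_len(C), ] <- tcrossprod(ca$slices[[si]], dY)
      dsl <- ca$W[off + seq_len(C), , drop = FALSE] %*% dY
      dim(dsl) <- c(C, oh, ow, N)
      dxp[, rows, cls, ] <- dxp[, rows, cls, , drop = FALSE] + dsl
      off <- off + C
    }
  }
  dx <- if (ca$pad > 0)
    dxp[, ca$pad + seq_len(ca$in_dim[2]), ca$pad + seq_len(ca$in_dim[3]), ,
        drop = FALSE]
  else dxp
  list(dx = dx, grads = list(W = dW))
}

# ---- batch normalization ----------------------------------------------------
#
# Channel-first layout: per-channel statistics are rowSums over a free
# reshape, and broadcasting is plain vector recycling.

bn_init <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C),
       run_mean = rep(0, C), run_var = rep(1, C))
}

ch_sums <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1], prod(d[-1]))
  rowSums(x)
}

bn_fwd <- function(x, p, training, momentum = 0.1, eps = 1e-5) {
  C <- dim(x)[1]
  M <- prod(dim(x)[-1])
  if (training) {
    m <- ch_sums(x) / M
    xc <- x - m
    v <- ch_sums(xc * xc) / M
    p$run_mean <- (1 - momentum) * p$run_mean + momentum * m
    p$run_var <- (1 - momentum) * p$run_var + momentum * v * M / max(M - 1, 1)
  } else {
    m <- p$run_mean
    v <- p$run_var
    xc <- x - m
  }
  isd <- 1 / sqrt(v + eps)
  xhat <- xc * isd
  out <- xhat * p$gamma + p$beta
  list(out = out, state = p[c("run_mean", "run_var")],
       cache = list(xhat = xhat, isd = isd, gamma = p$gamma, M = M,
                    training = training))
}

bn_bwd <- function(dy, cache) {
  ca <- cache
  dgamma <- ch_sums(dy * ca$xhat)
  dbeta <- ch_sums(dy)
  dxhat <- dy * ca$gamma
  if (ca$training) {
    s1 <- ch_sums(dxhat)
    s2 <- ch_sums(dxhat * ca$xhat)
    dx <- (dxhat - s1 / ca$M - ca$xhat * (s2 / ca$M)) * ca$isd
  } else {
    dx <- dxhat * ca$isd
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# ---- pointwise and pooling --------------------------------------------------

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dy, cache) dy * cache

# Global average pool: (C, H, W, N) -> (N, C).
gap_fwd <- function(x) {
  d <- dim(x)
  HW <- d[2] * d[3]
  dim(x) <- c(d[1] * HW, d[4])
  # mean over spatial positions per (channel, image)
  out <- matrix(0, d[4], d[1])
  for (n in seq_len(d[4]))
    out[n, ] <- rowSums(matrix(x[, n], d[1], HW)) / HW
  list(out = out, cache = d)
}

gap_bwd <- function(dy, cache) {
  d <- cache
  HW <- d[2] * d[3]
  bc <- t(dy)[, rep(seq_len(d[4]), each = HW), drop = FALSE] / HW
  dim(bc) <- d
  bc
}

# ---- fully connected --------------------------------------------------------

fc_init <- function(in_c, out_c) {
  list(W = matrix(rnorm(in_c * out_c, sd = sqrt(2 / in_c)), in_c, out_c),
       b = rep(0, out_c))
}

fc_fwd <- function(x, p) {
  list(out = sweep(x %*% p$W, 2, p$b, "+"), cache = list(x = x, W = p$W))
}

fc_bwd <- function(dy, cache) {
  list(dx = tcrossprod(dy, cache$W),
       grads = list(W = crossprod(cache$x, dy), b = colSums(dy)))
}

# ---- layer normalization over the feature dimension of an (N, D) matrix -----

ln_init <- function(D) list(gamma = rep(1, D), beta = rep(0, D))

ln_fwd <- function(x, p, eps = 1e-5) {
  m <- rowMeans(x)
  xc <- x - m
  v <- rowMeans(xc * xc)
  isd <- 1 / sqrt(v + eps)
  xhat <- xc * isd
  out <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  list(out = out, cache = list(xhat = xhat, isd = isd, gamma = p$gamma))
}

ln_bwd <- function(dy, cache) {
  ca <- cache
  dgamma <- colSums(dy * ca$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, ca$gamma, "*")
  dx <- (dxhat - rowMeans(dxhat) - ca$xhat * rowMeans(dxhat * ca$xhat)) * ca$isd
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# ---- softmax ----------------------------------------------------------------

# Numerically stabilized row softmax of an (N, C) matrix.
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
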
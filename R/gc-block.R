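# Global context (GC) attention block.
#
# Three stages, applied to a (C, H, W, N) feature map:
#   1. context modeling — a 1x1 convolution scores every spatial position,
#      softmax over all H*W positions turns the scores into an attention map,
#      and the attention-weighted sum of the input pools one global context
#      vector (length C) per image;
#   2. transform — a two-layer channel bottleneck (reduce by `reduction`,
#      layer-normalize + ReLU, expand back) maps the context vector;
#   3. fusion — the transformed vector is combined with the input at every
#      spatial position, by broadcast addition (default) or element-wise
#      multiplication.
#
# The final transform layer is zero-initialized, so with additive fusion the
# block is exactly the identity at initialization and training moves it away
# from the identity only as far as the data asks.

gc_init <- function(C, reduction, zero_final = TRUE) {
  if (reduction < 1) abort_config("gc reduction ratio must be >= 1")
  if (C %% reduction != 0)
    abort_config(sprintf(
      "gc block channels (%d) not divisible by reduction ratio (%d)", C, reduction))
  Cr <- C %/% reduction
  f2 <- fc_init(Cr, C)
  if (zero_final) {
    f2$W[] <- 0
    f2$b[] <- 0
  }
  list(
    attn_w = matrix(rnorm(C, sd = sqrt(1 / C)), C, 1),
    fc1 = fc_init(C, Cr),
    ln = ln_init(Cr),
    fc2 = f2
  )
}

# Broadcast an (N, C) matrix over HW spatial positions -> (C, H, W, N).
bcast_spatial <- function(delta, d) {
  HW <- d[2] * d[3]
  bc <- t(delta)[, rep(seq_len(d[4]), each = HW), drop = FALSE]
  dim(bc) <- d
  bc
}

# Sum a (C, H, W, N) array over spatial positions -> (N, C).
reduce_spatial <- function(a, d) {
  HW <- d[2] * d[3]
  dim(a) <- c(d[1] * HW, d[4])
  out <- matrix(0, d[4], d[1])
  for (n in seq_len(d[4])) out[n, ] <- rowSums(matrix(a[, n], d[1], HW))
  out
}

gc_fwd <- function(x, p, fusion = "add", training = TRUE) {
  d <- dim(x)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  HW <- H * W
  Mx <- x
  dim(Mx) <- c(C, HW * N)
  A <- matrix(crossprod(Mx, p$attn_w), HW, N)         # attention logits
  A <- sweep(A, 2, apply(A, 2, max), "-")
  E <- exp(A)
  attn <- sweep(E, 2, colSums(E), "/")                # (HW, N), cols sum to 1
  attn_row <- rep(as.numeric(attn), each = C)
  ctx <- reduce_spatial(x * attn_row, d)              # (N, C)
  f1 <- fc_fwd(ctx, p$fc1)
  l1 <- ln_fwd(f1$out, p$ln)
  r1 <- relu_fwd(l1$out)
  f2 <- fc_fwd(r1$out, p$fc2)
  delta <- f2$out                                     # (N, C)
  bcast <- bcast_spatial(delta, d)
  out <- switch(fusion,
    add = x + bcast,
    multiply = x * bcast,
    abort_config(sprintf("unknown gc fusion mode '%s'", fusion)))
  list(out = out, attn = attn,
       cache = list(x = x, attn = attn, attn_row = attn_row, d = d,
                    fusion = fusion, bcast = bcast, attn_w = p$attn_w,
                    f1 = f1$cache, l1 = l1$cache, r1 = r1$cache,
                    f2 = f2$cache))
}

gc_bwd <- function(dy, cache) {
  ca <- cache
  d <- ca$d
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  if (ca$fusion == "add") {
    dx <- dy
    ddelta <- reduce_spatial(dy, d)
  } else {
    dx <- dy * ca$bcast
    ddelta <- reduce_spatial(dy * ca$x, d)
  }
  g <- list()
  b2 <- fc_bwd(ddelta, ca$f2)
  g$fc2 <- b2$grads
  dr <- relu_bwd(b2$dx, ca$r1)
  bl <- ln_bwd(dr, ca$l1)
  g$ln <- bl$grads
  b1 <- fc_bwd(bl$dx, ca$f1)
  g$fc1 <- b1$grads
  dctx <- b1$dx                                       # (N, C)
  dctx_bc <- bcast_spatial(dctx, d)                   # (C, H, W, N)
  dx_ctx <- dctx_bc * ca$attn_row
  # dattn[hw, n] = sum_c x[c, hw, n] * dctx[n, c]
  prod_ <- ca$x * dctx_bc
  dim(prod_) <- c(C, HW * N)
  dattn <- matrix(colSums(prod_), HW, N)
  dA <- ca$attn * sweep(dattn, 2, colSums(ca$attn * dattn), "-")
  # dx from attention logits: dA[hw, n] * w[c]
  dA_row <- rep(as.numeric(dA), each = C)
  dx_attn <- dA_row * as.numeric(ca$attn_w)
  dim(dx_attn) <- d
  Mx <- ca$x
  dim(Mx) <- c(C, HW * N)
  g$attn_w <- Mx %*% matrix(as.numeric(dA), ncol = 1)
  list(dx = dx + dx_ctx + dx_attn, grads = g)
}

#' Apply a global context block to a feature map
#'
#' Runs the three-stage global context attention block — context modeling
#' (normalized spatial attention pooling), a channel-bottleneck transform,
#' and fusion back into every spatial position — over a batch of feature
#' maps. Output shape equals input shape.
#'
#' @param feature_map Numeric array of shape `(C, H, W, N)` (channels,
#'   spatial rows, spatial columns, batch).
#' @param params Block parameters from an internal initializer; if `NULL`, a
#'   fresh block is initialized (seeded by `seed`) with its final transform
#'   layer at zero, making the additive block the exact identity.
#' @param fusion `"add"` (broadcast addition, default) or `"multiply"`
#'   (element-wise product).
#' @param reduction Channel reduction ratio of the transform bottleneck;
#'   channels must be divisible by it.
#' @param seed Seed for parameter initialization when `params` is `NULL`.
#' @return A list with `out` (array, same shape as the input) and `attn`
#'   (the `(H*W, N)` spatial attention map; each column sums to 1).
#' @examples
#' x <- array(rnorm(4 * 8 * 8 * 2), c(4, 8, 8, 2))
#' y <- gc_block_forward(x, reduction = 2)
#' all.equal(y$out, x)  # identity at initialization under additive fusion
#' @export
gc_block_forward <- function(feature_map, params = NULL, fusion = "add",
                             reduction = 4, seed = 1) {
  d <- dim(feature_map)
  if (length(d) != 4L) abort_contract("feature_map must be a (C, H, W, N) array")
  if (d[2] * d[3] < 1L) abort_contract("feature_map has empty spatial extent")
  if (is.null(params)) params <- with_seed(seed, gc_init(d[1], reduction))
  f <- gc_fwd(feature_map, params, fusion = fusion, training = FALSE)
  list(out = f$out, attn = f$attn)
}
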
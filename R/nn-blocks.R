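# Residual building blocks assembled from the ops in nn-ops.R.
#
# A block is conv3x3(stride s) -> BN -> ReLU -> conv3x3 -> BN, added to a
# shortcut (identity, or 1x1 conv + BN when the shape changes), then ReLU.

res_block_init <- function(in_c, out_c, stride) {
  p <- list(
    conv1 = conv_init(3L, in_c, out_c),
    bn1 = bn_init(out_c),
    conv2 = conv_init(3L, out_c, out_c),
    bn2 = bn_init(out_c)
  )
  p$conv1$stride <- as.integer(stride)
  if (stride != 1L || in_c != out_c) {
    pr <- conv_init(1L, in_c, out_c)
    pr$stride <- as.integer(stride)
    p$proj <- pr
    p$bnp <- bn_init(out_c)
  }
  p
}

res_block_fwd <- function(x, p, training) {
  c1 <- conv_fwd(x, p$conv1)
  b1 <- bn_fwd(c1$out, p$bn1, training)
  r1 <- relu_fwd(b1$out)
  c2 <- conv_fwd(r1$out, p$conv2)
  b2 <- bn_fwd(c2$out, p$bn2, training)
  if (!is.null(p$proj)) {
    cp <- conv_fwd(x, p$proj)
    bp <- bn_fwd(cp$out, p$bnp, training)
    sc <- bp$out
  } else {
    cp <- NULL; bp <- NULL
    sc <- x
  }
  r2 <- relu_fwd(b2$out + sc)
  state <- list(bn1 = b1$state, bn2 = b2$state)
  if (!is.null(bp)) state$bnp <- bp$state
  list(out = r2$out, state = state,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, cp = cp$cache,
                    bp = bp$cache, r2 = r2$cache, has_proj = !is.null(p$proj)))
}

res_block_bwd <- function(dy, cache) {
  d <- relu_bwd(dy, cache$r2)
  g <- list()
  bb2 <- bn_bwd(d, cache$b2)
  g$bn2 <- bb2$grads
  cb2 <- conv_bwd(bb2$dx, cache$c2)
  g$conv2 <- cb2$grads
  dr1 <- relu_bwd(cb2$dx, cache$r1)
  bb1 <- bn_bwd(dr1, cache$b1)
  g$bn1 <- bb1$grads
  cb1 <- conv_bwd(bb1$dx, cache$c1)
  g$conv1 <- cb1$grads
  dx <- cb1$dx
  if (cache$has_proj) {
    bbp <- bn_bwd(d, cache$bp)
    g$bnp <- bbp$grads
    cbp <- conv_bwd(bbp$dx, cache$cp)
    g$proj <- cbp$grads
    dx <- dx + cbp$dx
  } else {
    dx <- dx + d
  }
  list(dx = dx, grads = g)
}

# A stage is a list of residual blocks applied in sequence.

stage_init <- function(in_c, out_c, n_blocks, stride) {
  lapply(seq_len(n_blocks), function(b) {
    res_block_init(if (b == 1L) in_c else out_c, out_c,
                   if (b == 1L) stride else 1L)
  })
}

stage_fwd <- function(x, blocks, training) {
  caches <- vector("list", length(blocks))
  states <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    f <- res_block_fwd(x, blocks[[b]], training)
    x <- f$out
    caches[[b]] <- f$cache
    states[[b]] <- f$state
  }
  list(out = x, caches = caches, states = states)
}

stage_bwd <- function(dy, caches) {
  grads <- vector("list", length(caches))
  for (b in rev(seq_along(caches))) {
    bk <- res_block_bwd(dy, caches[[b]])
    dy <- bk$dx
    grads[[b]] <- bk$grads
  }
  list(dx = dy, grads = grads)
}

# Merge BN running-stat updates produced by a forward pass back into a
# parameter subtree (run stats are state, not trained parameters).
merge_bn_state <- function(params, state) {
  for (nm in names(state)) {
    if (is.null(state[[nm]])) next
    if (identical(sort(names(state[[nm]])), c("run_mean", "run_var"))) {
      params[[nm]]$run_mean <- state[[nm]]$run_mean
      params[[nm]]$run_var <- state[[nm]]$run_var
    } else {
      params[[nm]] <- merge_bn_state(params[[nm]], state[[nm]])
    }
  }
  params
}

merge_stage_state <- function(blocks, states) {
  for (b in seq_along(states)) blocks[[b]] <- merge_bn_state(blocks[[b]], states[[b]])
  blocks
}
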
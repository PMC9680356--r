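# Multi-exit student network and frozen teacher wrapper.
#
# The student is a staged residual backbone with a classifier exit after each
# stage. Every exit branch applies (optionally) a global context block, then a
# bottleneck that downsamples/projects the feature map to the deepest stage's
# feature shape, then global average pooling and a fully connected head. The
# deepest exit is the backbone's own classifier path, preceded by its own GC
# block; its post-GC feature map is the target shape (and feature target) that
# shallower exits are unified against.

ARCHS <- list(
  # CIFAR-style 3x3 stem; widths/blocks follow the 18-layer residual design
  resnet18 = list(stem_width = 64L, stem_stride = 1L,
                  widths = c(64L, 128L, 256L, 512L),
                  blocks = c(2L, 2L, 2L, 2L), strides = c(1L, 2L, 2L, 2L)),
  # widened 18-layer network used as the default heavyweight teacher
  resnet18_w96 = list(stem_width = 96L, stem_stride = 1L,
                      widths = c(96L, 192L, 384L, 768L),
                      blocks = c(2L, 2L, 2L, 2L), strides = c(1L, 2L, 2L, 2L)),
  # reduced-depth backbone for desk-scale experiments on small images:
  # downsampling at the stem and at every stage keeps feature maps small
  tiny = list(stem_width = 4L, stem_stride = 2L,
              widths = c(4L, 8L, 16L, 32L),
              blocks = c(1L, 1L, 1L, 1L), strides = c(2L, 2L, 2L, 2L)),
  # wider reduced-depth network, the desk-scale teacher
  tiny_wide = list(stem_width = 8L, stem_stride = 2L,
                   widths = c(8L, 16L, 32L, 64L),
                   blocks = c(1L, 1L, 1L, 1L), strides = c(2L, 2L, 2L, 2L))
)

#' Student network configuration
#'
#' Collects the architecture hyperparameters of the multi-exit student:
#' which staged residual backbone to use, how many exits to attach, which
#' exits carry a global context (GC) attention block, the channel reduction
#' ratio of the GC transform, the fusion operator, and the class count.
#'
#' @param backbone_id One of `"resnet18"` (default; 18-layer residual
#'   backbone), `"resnet18_w96"` (widened variant), `"tiny"` (reduced-depth
#'   backbone for small images), `"tiny_wide"` (wider reduced-depth variant).
#' @param n_exits Number of classifier exits (2 to 4); exit m taps the
#'   backbone after stage m, exit `n_exits` is the deepest (backbone) head.
#' @param num_classes Number of output classes C.
#' @param gc_on_exits Integer vector of exits carrying a GC block
#'   (default all).
#' @param gc_reduction_ratio Channel reduction in the GC transform; must
#'   divide every tapped stage's width. Default 16 for the full-width
#'   backbones, 4 for the reduced-depth ones.
#' @param fusion_mode `"add"` or `"multiply"` — how the transformed context
#'   vector is fused back into the feature map.
#' @return A `student_config` list.
#' @export
student_config <- function(backbone_id = "resnet18", n_exits = 4L,
                           num_classes = 5L, gc_on_exits = seq_len(n_exits),
                           gc_reduction_ratio = NULL, fusion_mode = "add") {
  if (!backbone_id %in% names(ARCHS))
    abort_config(sprintf("unknown backbone_id '%s'", backbone_id))
  arch <- ARCHS[[backbone_id]]
  n_exits <- as.integer(n_exits)
  if (n_exits < 2L || n_exits > length(arch$widths))
    abort_config(sprintf(
      "n_exits must be between 2 and the number of backbone stages (%d), got %d",
      length(arch$widths), n_exits))
  if (is.null(gc_reduction_ratio))
    gc_reduction_ratio <- if (startsWith(backbone_id, "tiny")) 2L else 16L
  if (gc_reduction_ratio < 1) abort_config("gc_reduction_ratio must be >= 1")
  if (!fusion_mode %in% c("add", "multiply"))
    abort_config("fusion_mode must be 'add' or 'multiply'")
  structure(list(backbone_id = backbone_id, n_exits = n_exits,
                 num_classes = as.integer(num_classes),
                 gc_on_exits = as.integer(gc_on_exits),
                 gc_reduction_ratio = as.integer(gc_reduction_ratio),
                 fusion_mode = fusion_mode, arch = arch),
            class = "student_config")
}

# Backbone stage tapped by exit m: the last n_exits stages carry exits, so
# the deepest exit is always the backbone's own head path.
exit_stage <- function(config, m) {
  length(config$arch$widths) - config$n_exits + m
}

# Depth of the stride-2 bottleneck stack for an exit tapping stage s: log2 of
# the spatial ratio between stage s's output and the deepest stage's output.
bottleneck_depth <- function(arch, s, n_stages = length(arch$widths)) {
  if (s >= n_stages) return(0L)
  down <- sum(arch$strides[(s + 1):n_stages] == 2L)
  as.integer(down)
}

#' Build the multi-exit student network
#'
#' Initializes a multi-exit student per the configuration: a staged residual
#' backbone, and after each tapped stage an exit branch of GC block,
#' scale-unifying bottleneck, global average pooling, and a fully connected
#' head. Weights are He-initialized; GC final transform layers start at zero
#' so additive-fusion blocks begin as identities.
#'
#' @param config A [student_config()].
#' @param seed Integer seed for weight initialization.
#' @param with_exits If `FALSE`, build the plain backbone with a single head
#'   (used for teachers and for parameter-count comparisons).
#' @return A `cyto_model` list with elements `config`, `params`, `frozen`.
#' @export
build_student <- function(config = student_config(), seed = 1,
                          with_exits = TRUE) {
  arch <- config$arch
  ns <- length(arch$widths)
  params <- with_seed(derive_seed(seed, "init"), {
    p <- list()
    p$stem <- list(conv = conv_init(3L, 3L, arch$stem_width),
                   bn = bn_init(arch$stem_width))
    p$stem$conv$stride <- arch$stem_stride
    in_c <- arch$stem_width
    p$stages <- vector("list", ns)
    for (s in seq_len(ns)) {
      p$stages[[s]] <- stage_init(in_c, arch$widths[s], arch$blocks[s],
                                  arch$strides[s])
      in_c <- arch$widths[s]
    }
    if (with_exits) {
      p$exits <- vector("list", config$n_exits)
      top_w <- arch$widths[ns]
      for (m in seq_len(config$n_exits)) {
        s_tap <- exit_stage(config, m)
        stage_w <- arch$widths[s_tap]
        ex <- list()
        if (m %in% config$gc_on_exits)
          ex$gc <- gc_init(stage_w, config$gc_reduction_ratio)
        depth <- bottleneck_depth(arch, s_tap, ns)
        if (depth > 0L) {
          # stride-2 residual units at the tap width, then a 1x1 channel
          # projection to the deepest stage's width: unifies both spatial
          # scale and channel count at a small parameter cost
          ex$bottleneck <- lapply(seq_len(depth), function(k)
            res_block_init(stage_w, stage_w, 2L))
        }
        if (stage_w != top_w) {
          ex$proj <- conv_init(1L, stage_w, top_w)
          ex$proj_bn <- bn_init(top_w)
        }
        ex$head <- fc_init(top_w, config$num_classes)
        p$exits[[m]] <- ex
      }
    } else {
      p$head <- fc_init(arch$widths[ns], config$num_classes)
    }
    p
  })
  structure(list(config = config, params = params, frozen = FALSE,
                 with_exits = with_exits),
            class = "cyto_model")
}

# Forward through stem + all stages; returns per-stage outputs.
backbone_fwd <- function(params, x, training) {
  cs <- conv_fwd(x, params$stem$conv)
  bs <- bn_fwd(cs$out, params$stem$bn, training)
  rs <- relu_fwd(bs$out)
  h <- rs$out
  ns <- length(params$stages)
  stage_out <- vector("list", ns)
  stage_caches <- vector("list", ns)
  stage_states <- vector("list", ns)
  for (s in seq_len(ns)) {
    f <- stage_fwd(h, params$stages[[s]], training)
    h <- f$out
    stage_out[[s]] <- h
    stage_caches[[s]] <- f$caches
    stage_states[[s]] <- f$states
  }
  list(stage_out = stage_out,
       cache = list(cs = cs$cache, bs = bs$cache, rs = rs$cache,
                    stages = stage_caches),
       state = list(stem_bn = bs$state, stages = stage_states))
}

# Exit branch forward: optional GC -> bottleneck -> (feature) -> GAP -> head.
exit_fwd <- function(feat, ex, fusion, training) {
  cache <- list(has_gc = !is.null(ex$gc), nb = length(ex$bottleneck),
                has_proj = !is.null(ex$proj))
  if (cache$has_gc) {
    g <- gc_fwd(feat, ex$gc, fusion = fusion, training = training)
    feat <- g$out
    cache$gc <- g$cache
  }
  states <- list()
  if (cache$nb > 0L) {
    bc <- vector("list", cache$nb)
    bs <- vector("list", cache$nb)
    for (k in seq_len(cache$nb)) {
      f <- res_block_fwd(feat, ex$bottleneck[[k]], training)
      feat <- f$out
      bc[[k]] <- f$cache
      bs[[k]] <- f$state
    }
    cache$bottleneck <- bc
    states$bottleneck <- bs
  }
  if (cache$has_proj) {
    pc <- conv_fwd(feat, ex$proj)
    pb <- bn_fwd(pc$out, ex$proj_bn, training)
    pr <- relu_fwd(pb$out)
    feat <- pr$out
    cache$proj <- pc$cache
    cache$proj_bn <- pb$cache
    cache$proj_relu <- pr$cache
    states$proj_bn <- pb$state
  }
  gp <- gap_fwd(feat)
  hd <- fc_fwd(gp$out, ex$head)
  cache$gap <- gp$cache
  cache$head <- hd$cache
  list(logits = hd$out, feature = feat, cache = cache, state = states)
}

exit_bwd <- function(dlogits, dfeature, cache) {
  g <- list()
  hb <- fc_bwd(dlogits, cache$head)
  g$head <- hb$grads
  dfeat <- gap_bwd(hb$dx, cache$gap)
  if (!is.null(dfeature)) dfeat <- dfeat + dfeature
  if (cache$has_proj) {
    dpr <- relu_bwd(dfeat, cache$proj_relu)
    pbb <- bn_bwd(dpr, cache$proj_bn)
    g$proj_bn <- pbb$grads
    pcb <- conv_bwd(pbb$dx, cache$proj)
    g$proj <- pcb$grads
    dfeat <- pcb$dx
  }
  if (cache$nb > 0L) {
    gb <- vector("list", cache$nb)
    for (k in rev(seq_len(cache$nb))) {
      bk <- res_block_bwd(dfeat, cache$bottleneck[[k]])
      dfeat <- bk$dx
      gb[[k]] <- bk$grads
    }
    g$bottleneck <- gb
  }
  if (cache$has_gc) {
    gg <- gc_bwd(dfeat, cache$gc)
    dfeat <- gg$dx
    g$gc <- gg$grads
  }
  list(dx = dfeat, grads = g)
}

#' Forward pass of a multi-exit model
#'
#' Runs a batch through the student and collects every exit's raw logits and
#' scale-unified feature map (the bundle used by the distillation losses).
#'
#' @param model A `cyto_model` from [build_student()].
#' @param x Input batch, channel-first array `(3, H, W, N)` with values
#'   typically normalized (see [as_image_batch()] via the training
#'   functions).
#' @param training Logical; `TRUE` uses batch statistics in the normalization
#'   layers and records the caches needed for the backward pass.
#' @return An `exit_bundle`: list with `logits` (list of `(N, C)` matrices,
#'   shallow to deep), `features` (list of feature arrays, all of the deepest
#'   exit's shape), `n`, and — when `training` — `caches` and `state`.
#' @export
student_forward <- function(model, x, training = FALSE) {
  if (!model$with_exits)
    abort_contract("model was built without exits; use teacher_forward()")
  p <- model$params
  fusion <- model$config$fusion_mode
  bb <- backbone_fwd(p, x, training)
  n <- model$config$n_exits
  logits <- vector("list", n)
  feats <- vector("list", n)
  ecaches <- vector("list", n)
  estates <- vector("list", n)
  for (m in seq_len(n)) {
    ef <- exit_fwd(bb$stage_out[[exit_stage(model$config, m)]],
                   p$exits[[m]], fusion, training)
    logits[[m]] <- ef$logits
    feats[[m]] <- ef$feature
    ecaches[[m]] <- ef$cache
    estates[[m]] <- ef$state
  }
  out <- list(logits = logits, features = feats, n = n,
              C = model$config$num_classes)
  if (training) {
    out$caches <- list(backbone = bb$cache, exits = ecaches)
    out$state <- list(backbone = bb$state, exits = estates)
  }
  structure(out, class = "exit_bundle")
}

# Backward pass: gradients of a scalar loss wrt every exit's logits and
# unified features -> full parameter-gradient tree.
student_backward <- function(model, bundle, dlogits, dfeatures) {
  caches <- bundle$caches
  n <- bundle$n
  p <- model$params
  g <- list(exits = vector("list", n))
  dstage <- vector("list", length(p$stages))
  for (m in seq_len(n)) {
    eb <- exit_bwd(dlogits[[m]], dfeatures[[m]], caches$exits[[m]])
    g$exits[[m]] <- eb$grads
    s_tap <- exit_stage(model$config, m)
    dstage[[s_tap]] <- if (is.null(dstage[[s_tap]])) eb$dx
                       else dstage[[s_tap]] + eb$dx
  }
  ns <- length(p$stages)
  dy <- NULL
  g$stages <- vector("list", ns)
  for (s in rev(seq_len(ns))) {
    d <- dstage[[s]]
    if (is.null(d)) d <- 0
    dy <- if (is.null(dy)) d else dy + d
    sb <- stage_bwd(dy, caches$backbone$stages[[s]])
    g$stages[[s]] <- sb$grads
    dy <- sb$dx
  }
  drs <- relu_bwd(dy, caches$backbone$rs)
  bbs <- bn_bwd(drs, caches$backbone$bs)
  cbs <- conv_bwd(bbs$dx, caches$backbone$cs)
  g$stem <- list(conv = cbs$grads, bn = bbs$grads)
  g
}

# Fold the BN running-stat updates recorded in a training forward back into
# the model.
apply_bn_state <- function(model, state) {
  p <- model$params
  p$stem$bn$run_mean <- state$backbone$stem_bn$run_mean
  p$stem$bn$run_var <- state$backbone$stem_bn$run_var
  for (s in seq_along(p$stages))
    p$stages[[s]] <- merge_stage_state(p$stages[[s]], state$backbone$stages[[s]])
  for (m in seq_along(state$exits)) {
    st <- state$exits[[m]]
    if (!is.null(st$bottleneck))
      p$exits[[m]]$bottleneck <-
        merge_stage_state(p$exits[[m]]$bottleneck, st$bottleneck)
    if (!is.null(st$proj_bn)) {
      p$exits[[m]]$proj_bn$run_mean <- st$proj_bn$run_mean
      p$exits[[m]]$proj_bn$run_var <- st$proj_bn$run_var
    }
  }
  model$params <- p
  model
}

#' Unify a shallow exit feature map to the deepest exit's shape
#'
#' Applies the bottleneck transform of exit `m` — a stack of stride-2
#' residual units (one per factor-of-two spatial ratio) followed by a 1x1
#' channel projection to the deepest stage's width — so shallow features
#' become comparable with the deepest exit's feature map in the
#' self-distillation feature loss. For the deepest exit the transform is the
#' identity.
#'
#' @param feature Input feature array, channel-first `(C, H, W, N)`.
#' @param model A `cyto_model`.
#' @param m Exit index.
#' @return The unified feature array (the deepest stage's shape).
#' @export
bottleneck_forward <- function(feature, model, m) {
  ex <- model$params$exits[[m]]
  nb <- length(ex$bottleneck)
  if (nb == 0L && is.null(ex$proj)) return(feature)
  d <- dim(feature)
  need <- 2^nb
  if (d[2] %% need != 0 || d[3] %% need != 0)
    abort_config(sprintf(
      "exit %d feature map %dx%d is not divisible by the bottleneck downsampling factor %d",
      m, d[2], d[3], need))
  for (k in seq_len(nb)) feature <- res_block_fwd(feature, ex$bottleneck[[k]],
                                                  training = FALSE)$out
  if (!is.null(ex$proj)) {
    pc <- conv_fwd(feature, ex$proj)
    pb <- bn_fwd(pc$out, ex$proj_bn, training = FALSE)
    feature <- relu_fwd(pb$out)$out
  }
  feature
}

#' Build a frozen teacher model
#'
#' Wraps a plain (single-head) classifier as a frozen teacher: parameters are
#' marked non-trainable and the forward pass yields logits only. Either an
#' architecture id (fresh weights) or a checkpoint path saved by
#' [save_checkpoint()] may be given.
#'
#' @param architecture_id Backbone id (see [student_config()]); default
#'   `"resnet18_w96"`, a heavyweight network wider than the student.
#' @param num_classes Class count C.
#' @param checkpoint_path Optional path to a checkpoint; its weights and
#'   config replace the fresh ones. Class count must match.
#' @param seed Seed for fresh initialization.
#' @return A frozen `cyto_model`.
#' @export
build_teacher <- function(architecture_id = "resnet18_w96", num_classes = 5L,
                          checkpoint_path = NULL, seed = 1) {
  if (!is.null(checkpoint_path)) {
    model <- load_checkpoint(checkpoint_path)
    if (model$config$num_classes != num_classes)
      abort_config(sprintf(
        "checkpoint has %d classes, requested %d; mismatched head tensors: head$W, head$b",
        model$config$num_classes, num_classes))
  } else {
    cfg <- student_config(backbone_id = architecture_id,
                          num_classes = num_classes)
    model <- build_student(cfg, seed = seed, with_exits = FALSE)
  }
  model$frozen <- TRUE
  model
}

#' Forward pass of a plain (teacher or baseline) classifier
#'
#' @param model A `cyto_model` built with a single head.
#' @param x Input batch, channel-first `(3, H, W, N)`.
#' @param training Use batch statistics and keep caches (ignored for frozen
#'   models, which always run in inference mode).
#' @return List with `logits` `(N, C)` and, when training, `caches`/`state`.
#' @export
teacher_forward <- function(model, x, training = FALSE) {
  if (model$with_exits)
    abort_contract("model has exits; use student_forward()")
  if (model$frozen) training <- FALSE
  bb <- backbone_fwd(model$params, x, training)
  top <- bb$stage_out[[length(model$params$stages)]]
  gp <- gap_fwd(top)
  hd <- fc_fwd(gp$out, model$params$head)
  out <- list(logits = hd$out)
  if (training) {
    out$caches <- list(backbone = bb$cache, gap = gp$cache, head = hd$cache)
    out$state <- bb$state
  }
  out
}

# Backward for the plain classifier (used in CE pretraining).
teacher_backward <- function(model, caches, dlogits) {
  hb <- fc_bwd(dlogits, caches$head)
  dfeat <- gap_bwd(hb$dx, caches$gap)
  p <- model$params
  ns <- length(p$stages)
  g <- list(head = hb$grads, stages = vector("list", ns))
  dy <- dfeat
  for (s in rev(seq_len(ns))) {
    sb <- stage_bwd(dy, caches$backbone$stages[[s]])
    g$stages[[s]] <- sb$grads
    dy <- sb$dx
  }
  drs <- relu_bwd(dy, caches$backbone$rs)
  bbs <- bn_bwd(drs, caches$backbone$bs)
  cbs <- conv_bwd(bbs$dx, caches$backbone$cs)
  g$stem <- list(conv = cbs$grads, bn = bbs$grads)
  g
}

# ---- parameters and checkpoints ---------------------------------------------

# Trainable leaves of a parameter tree: everything except BN running stats
# and structural conv metadata (k, stride, pad).
trainable_leaves <- function(params, prefix = "") {
  out <- list()
  for (nm in names(params)) {
    v <- params[[nm]]
    key <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
    if (is.list(v)) out <- c(out, trainable_leaves(v, key))
    else if (is.numeric(v) &&
             !nm %in% c("run_mean", "run_var", "k", "stride", "pad"))
      out[[key]] <- v
  }
  # unnamed lists (stages/blocks) recurse positionally
  if (is.null(names(params))) {
    for (i in seq_along(params)) {
      key <- paste(prefix, i, sep = ".")
      out <- c(out, trainable_leaves(params[[i]], key))
    }
  }
  out
}

#' Count trainable parameters of a model
#'
#' @param model A `cyto_model`.
#' @return Integer count of trainable scalar parameters, with attribute
#'   `millions` (rounded to 2 decimals).
#' @export
count_parameters <- function(model) {
  n <- sum(vapply(trainable_leaves(model$params), length, numeric(1)))
  structure(as.integer(n), millions = round(n / 1e6, 2))
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the weights plus an echo of the configuration and
#' round-trip bit-exactly.
#'
#' @param model A `cyto_model`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path, version = 2L)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("checkpoint '%s' not found", path))
  readRDS(path)
}
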
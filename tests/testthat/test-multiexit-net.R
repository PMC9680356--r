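test_that("the exit bundle honours its shape contracts", {
  cfg <- student_config("tiny", n_exits = 4L, num_classes = 5L)
  model <- build_student(cfg, seed = 1)
  x <- array(rnorm(3 * 64 * 64 * 2), c(3, 64, 64, 2))
  b <- student_forward(model, x)
  expect_s3_class(b, "exit_bundle")
  expect_equal(b$n, 4L)
  for (m in 1:4) expect_equal(dim(b$logits[[m]]), c(2L, 5L))
  deep_shape <- dim(b$features[[4]])
  for (m in 1:4) expect_equal(dim(b$features[[m]]), deep_shape)
  # shape unification holds for every supported exit count
  for (ne in 2:4) {
    mne <- build_student(student_config("tiny", n_exits = ne,
                                        num_classes = 3L), seed = 2)
    bne <- student_forward(mne, array(rnorm(3 * 32 * 32 * 2),
                                      c(3, 32, 32, 2)))
    shp <- dim(bne$features[[ne]])
    for (m in seq_len(ne)) expect_equal(dim(bne$features[[m]]), shp)
  }
  expect_error(student_config("tiny", n_exits = 5L), "n_exits")
  expect_error(student_config("nope"), "backbone_id")
})

test_that("parameter counts order plain student < multi-exit < teacher", {
  cfg18 <- student_config("resnet18", num_classes = 5L)
  plain <- build_student(cfg18, seed = 1, with_exits = FALSE)
  multi <- build_student(cfg18, seed = 1)
  teacher <- build_teacher("resnet18_w96", num_classes = 5L, seed = 1)
  n_plain <- count_parameters(plain)
  n_multi <- count_parameters(multi)
  n_teacher <- count_parameters(teacher)
  expect_lt(n_plain, n_multi)
  expect_lt(n_multi, n_teacher)
  # independent traversal oracle: recursively sum every trainable tensor
  alt_count <- function(p) {
    if (is.list(p)) {
      nms <- names(p)
      tot <- 0
      for (i in seq_along(p)) {
        nm <- if (is.null(nms)) "" else nms[i]
        if (nm %in% c("run_mean", "run_var", "k", "stride", "pad")) next
        tot <- tot + alt_count(p[[i]])
      }
      tot
    } else if (is.numeric(p)) length(p) else 0
  }
  expect_equal(as.integer(alt_count(multi$params)), as.integer(n_multi))
})

test_that("a single fully connected head has the closed-form count", {
  p <- cytodistill:::with_seed(1, cytodistill:::fc_init(512L, 5L))
  expect_equal(length(p$W) + length(p$b), 512 * 5 + 5)
})

test_that("bottleneck unification: identity at the deepest exit, stride-2 depth elsewhere", {
  cfg <- student_config("tiny", n_exits = 4L, num_classes = 5L)
  model <- build_student(cfg, seed = 3)
  x <- array(rnorm(3 * 64 * 64 * 2), c(3, 64, 64, 2))
  b <- student_forward(model, x)
  # deepest exit: no bottleneck blocks, mu_n is the identity
  expect_equal(length(model$params$exits[[4]]$bottleneck), 0L)
  f <- array(rnorm(prod(dim(b$features[[4]]))), dim(b$features[[4]]))
  expect_identical(bottleneck_forward(f, model, 4L), f)
  # shallow exits: unit count equals log2 of the spatial ratio (oracle)
  arch <- cfg$arch
  spatial <- 64 / arch$stem_stride
  sizes <- numeric(4)
  for (s in 1:4) {
    spatial <- spatial / arch$strides[s]
    sizes[s] <- spatial
  }
  for (m in 1:3)
    expect_equal(length(model$params$exits[[m]]$bottleneck),
                 log2(sizes[m] / sizes[4]))
  # and bottleneck output matches the deepest feature shape
  f1 <- array(rnorm(prod(c(4, sizes[1], sizes[1], 2))),
              c(4, sizes[1], sizes[1], 2))
  expect_equal(dim(bottleneck_forward(f1, model, 1L)), dim(b$features[[4]]))
  expect_error(bottleneck_forward(array(0, c(4, 3, 3, 2)), model, 1L),
               "divisible")
})

test_that("additive zero-init gc leaves the deepest-exit logits equal to the plain backbone's", {
  # identity-at-init equivalence: with all gc transforms zero-initialized and
  # additive fusion, the multi-exit network's deepest exit must equal the
  # same backbone + head without any gc block
  cfg <- student_config("tiny", n_exits = 4L, num_classes = 5L)
  multi <- build_student(cfg, seed = 5)
  plain <- build_student(cfg, seed = 99, with_exits = FALSE)
  plain$params$stem <- multi$params$stem
  plain$params$stages <- multi$params$stages
  plain$params$head <- multi$params$exits[[4]]$head
  x <- array(rnorm(3 * 32 * 32 * 3), c(3, 32, 32, 3))
  b <- student_forward(multi, x)
  t <- teacher_forward(plain, x)
  expect_equal(b$logits[[4]], t$logits, tolerance = 1e-12)
})

test_that("two-exit toy forward matches an independent nested-loop computation", {
  cfg <- student_config("tiny", n_exits = 2L, num_classes = 3L,
                        gc_on_exits = integer(0))
  model <- build_student(cfg, seed = 6)
  set.seed(61)
  x <- array(rnorm(3 * 16 * 16 * 2), c(3, 16, 16, 2))
  got <- student_forward(model, x)

  # independent path: nested-loop convolution + plain-R bn/relu/pool/fc
  bn_eval <- function(z, bp) (z - bp$run_mean) / sqrt(bp$run_var + 1e-5) *
    bp$gamma + bp$beta
  block_eval <- function(z, bp, stride) {
    h <- pmax(bn_eval(naive_conv(z, bp$conv1$W, 3L, stride), bp$bn1), 0)
    h2 <- bn_eval(naive_conv(h, bp$conv2$W, 3L, 1L), bp$bn2)
    sc <- if (!is.null(bp$proj))
      bn_eval(naive_conv(z, bp$proj$W, 1L, stride, pad = 0L), bp$bnp)
    else z
    pmax(h2 + sc, 0)
  }
  p <- model$params
  h <- pmax(bn_eval(naive_conv(x, p$stem$conv$W, 3L, 2L), p$stem$bn), 0)
  arch <- cfg$arch
  feats <- vector("list", 4)
  for (s in 1:4) {
    h <- block_eval(h, p$stages[[s]][[1]], arch$strides[s])
    feats[[s]] <- h
  }
  head_eval <- function(f, hd) {
    pooled <- t(apply(f, 4, function(a) rowMeans(matrix(a, dim(f)[1]))))
    sweep(pooled %*% hd$W, 2, hd$b, "+")
  }
  # exit 1 taps stage 3 (two-exit model on a four-stage backbone), runs its
  # stride-2 bottleneck unit and 1x1 channel projection, then pools
  f1 <- block_eval(feats[[3]], p$exits[[1]]$bottleneck[[1]], 2L)
  f1 <- pmax(bn_eval(naive_conv(f1, p$exits[[1]]$proj$W, 1L, 1L, pad = 0L),
                     p$exits[[1]]$proj_bn), 0)
  expect_equal(got$logits[[1]], head_eval(f1, p$exits[[1]]$head),
               tolerance = 1e-8)
  expect_equal(got$logits[[2]], head_eval(feats[[4]], p$exits[[2]]$head),
               tolerance = 1e-8)
})

test_that("teachers are frozen and checkpoints round-trip bit-exactly", {
  teacher <- build_teacher("tiny_wide", num_classes = 5L, seed = 2)
  expect_true(teacher$frozen)
  x <- array(rnorm(3 * 32 * 32 * 2), c(3, 32, 32, 2))
  out1 <- teacher_forward(teacher, x)
  expect_equal(dim(out1$logits), c(2L, 5L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(teacher, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, teacher$params)
  reteacher <- build_teacher(checkpoint_path = path, num_classes = 5L)
  expect_identical(reteacher$params, teacher$params)
  expect_true(reteacher$frozen)
  expect_error(build_teacher(checkpoint_path = path, num_classes = 7L),
               "mismatch")
})
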
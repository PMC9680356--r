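test_that("the step schedule matches its closed form at every epoch", {
  cfg <- distill_config()
  expect_equal(lr_at_epoch(cfg, 0), 0.1)
  expect_equal(lr_at_epoch(cfg, 99), 0.1)
  expect_equal(lr_at_epoch(cfg, 100), 0.01)
  expect_equal(lr_at_epoch(cfg, 150), 0.001)
  expect_equal(lr_at_epoch(cfg, 179), 0.001)
  closed <- function(e) 0.1 * 0.1^sum(c(100, 150) <= e)
  expect_equal(lr_at_epoch(cfg, 0:179), vapply(0:179, closed, numeric(1)))
})

test_that("the configuration carries the study defaults and validates", {
  cfg <- distill_config()
  expect_equal(cfg$epochs, 180L)
  expect_equal(cfg$batch_size, 128L)
  expect_equal(cfg$lr, 0.1)
  expect_equal(cfg$lr_milestones, c(100L, 150L))
  expect_equal(cfg$lr_gamma, 0.1)
  expect_equal(cfg$weight_decay, 1e-4)
  expect_equal(cfg$momentum, 0.9)
  expect_equal(cfg$tau, 3)
  expect_equal(cfg$lam, 0.03)
  expect_error(distill_config(tau = 0), "tau")
  expect_error(distill_config(lam = -1), "lam")
  expect_error(distill_config(kl_direction = "both"), "kl_direction")
})

small_cfg <- function(epochs = 2L)
  distill_config(epochs = epochs, batch_size = 16L, lr = 0.05)

test_that("pretraining reduces the loss and is bit-reproducible", {
  ds <- tiny_dataset(n_per_class = 8, image_size = 32, seed = 3)
  drops <- 0L
  for (s in 1:3) {
    model <- build_student(student_config("tiny_wide", num_classes = 5L),
                           seed = s, with_exits = FALSE)
    fit <- pretrain(model, ds, small_cfg(), seed = s)
    if (fit$history$train_loss[2] < fit$history$train_loss[1])
      drops <- drops + 1L
    expect_true(all(is.finite(fit$history$train_loss)))
  }
  expect_gte(drops, 2L)
  model <- build_student(student_config("tiny_wide", num_classes = 5L),
                         seed = 1, with_exits = FALSE)
  f1 <- pretrain(model, ds, small_cfg(), seed = 9)
  f2 <- pretrain(model, ds, small_cfg(), seed = 9)
  expect_identical(f1$final_model$params, f2$final_model$params)
  expect_error(pretrain(build_student(student_config("tiny"), seed = 1),
                        ds, small_cfg()),
               "single-head")
})

test_that("transfer load copies the backbone and reinitializes heads", {
  ds <- tiny_dataset(n_per_class = 6, image_size = 32)
  src <- build_student(student_config("tiny", num_classes = 5L), seed = 1,
                       with_exits = FALSE)
  fit <- pretrain(src, ds, small_cfg(1L), seed = 1)
  student <- build_student(student_config("tiny", num_classes = 3L), seed = 2)
  moved <- transfer_load(student, fit, num_target_classes = 3L)
  expect_identical(moved$params$stem, fit$model$params$stem)
  expect_identical(moved$params$stages, fit$model$params$stages)
  rep <- attr(moved, "transfer_report")
  expect_true("stem" %in% rep$transferred)
  expect_equal(length(rep$reinitialized), 4L)
  # fresh heads differ from the untransferred student's
  expect_false(identical(moved$params$exits[[1]]$head,
                         student$params$exits[[1]]$head))
  x <- array(rnorm(3 * 32 * 32 * 2), c(3, 32, 32, 2))
  b <- student_forward(moved, x)
  expect_equal(dim(b$logits[[1]]), c(2L, 3L))
  # identical class counts with reinit disabled: full weight equality
  same <- transfer_load(build_student(student_config("tiny", num_classes = 5L),
                                      seed = 3, with_exits = FALSE),
                        fit, reinit_heads = FALSE)
  expect_identical(same$params, fit$model$params)
})

test_that("distillation honours the frozen-teacher contract and is reproducible", {
  ds <- tiny_dataset(n_per_class = 8, image_size = 32, seed = 5)
  teacher <- build_teacher("tiny_wide", num_classes = 5L, seed = 1)
  student <- build_student(student_config("tiny", num_classes = 5L), seed = 2)
  fit <- finetune_distill(student, teacher, ds, small_cfg(), seed = 4)
  expect_identical(fit$teacher_hash[["before"]], fit$teacher_hash[["after"]])
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_true(all(paste0("acc_exit", 1:4) %in% names(fit$history)))
  fit2 <- finetune_distill(student, teacher, ds, small_cfg(), seed = 4)
  expect_identical(fit$final_model$params, fit2$final_model$params)
  unfrozen <- teacher
  unfrozen$frozen <- FALSE
  expect_error(finetune_distill(student, unfrozen, ds, small_cfg(), seed = 1),
               "not frozen")
})

test_that("with tau 1, lambda 0 and no teacher the objective is plain multi-head CE", {
  ds <- tiny_dataset(n_per_class = 6, image_size = 32)
  student <- build_student(student_config("tiny", num_classes = 5L), seed = 6)
  x <- cytodistill:::as_image_batch(ds$image[1:8], norm_stats(ds))
  y <- ds$class_index[1:8]
  b <- student_forward(student, x, training = TRUE)
  # self-distillation at tau=1/lam=0 still carries KL(S_m, S_n); disable the
  # teacher path by feeding the deepest exit itself as "teacher": then the
  # KD KL at the deepest exit vanishes and each exit's CE terms remain
  ce_sum <- 0
  for (m in 1:4) ce_sum <- ce_sum + cross_entropy(soften(b$logits[[m]], 1), y)
  cfg <- distill_config(tau = 1, lam = 0, dedup_deep_ce = TRUE)
  tot <- total_loss(b, b$logits[[4]], y, cfg)
  kd_kls <- sum(tot$breakdown$kd_kl) + sum(tot$breakdown$sd_kl)
  expect_equal(tot$total - kd_kls, ce_sum + cross_entropy(
    soften(b$logits[[4]], 1), y), tolerance = 1e-9)
  expect_equal(tot$breakdown$kd_kl[4], 0, tolerance = 1e-12)
})

test_that("manifests are deterministic and round-trip through the loader", {
  cfg <- distill_config(tau = 3, lam = 0.03)
  ds <- tiny_dataset(n_per_class = 6, image_size = 32)
  fp <- dataset_fingerprint(ds)
  p1 <- withr::local_tempfile(fileext = ".yaml")
  p2 <- withr::local_tempfile(fileext = ".yaml")
  run_manifest(cfg, list(master = 7L), list(target = fp), p1)
  run_manifest(cfg, list(master = 7L), list(target = fp), p2)
  expect_identical(readLines(p1), readLines(p2))
  y <- yaml::read_yaml(p1)
  expect_equal(y$config$tau, 3)
  expect_equal(y$config$lam, 0.03)
  back <- load_config(p1)
  expect_equal(back[c("tau", "lam", "epochs", "batch_size", "lr",
                      "weight_decay", "momentum")],
               cfg[c("tau", "lam", "epochs", "batch_size", "lr",
                     "weight_decay", "momentum")])
})
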
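# Two-stage training: supervised pretraining on a source domain, then
# distillation fine-tuning of the multi-exit student under a frozen teacher.

#' Learning rate at a given epoch
#'
#' Step schedule: `lr * lr_gamma ^ (number of milestones <= epoch)` with
#' 0-based epochs, i.e. the rate is multiplied by `lr_gamma` at each
#' milestone epoch.
#'
#' @param cfg A [distill_config()].
#' @param epoch 0-based epoch index (vectorized).
#' @return Learning rate(s).
#' @export
lr_at_epoch <- function(cfg, epoch) {
  vapply(epoch, function(e) cfg$lr * cfg$lr_gamma^sum(cfg$lr_milestones <= e),
         numeric(1))
}

# ---- SGD with momentum + weight decay over a gradient tree ------------------

sgd_step <- function(params, grads, vel, lr, momentum, weight_decay) {
  if (is.null(grads)) return(list(params = params, vel = vel))
  if (is.list(grads)) {
    keys <- names(grads) %||% seq_along(grads)
    if (is.null(vel)) {
      vel <- vector("list", length(grads))
      names(vel) <- names(grads)
    }
    for (k in seq_along(keys)) {
      key <- keys[[k]]
      res <- sgd_step(params[[key]], grads[[k]], vel[[k]], lr, momentum,
                      weight_decay)
      params[[key]] <- res$params
      vel[[k]] <- res$vel
    }
    list(params = params, vel = vel)
  } else {
    if (is.null(vel)) vel <- grads * 0
    vel <- momentum * vel + grads + weight_decay * params
    list(params = params - lr * vel, vel = vel)
  }
}

# Minibatch index order for one epoch, seeded.
epoch_batches <- function(n, batch_size, seed) {
  idx <- with_seed(seed, sample.int(n))
  split(idx, ceiling(seq_along(idx) / batch_size))
}

# Exit probabilities over a dataset (eval mode, temperature-1 softmax).
infer_probs <- function(model, images, stats, batch_size = 64L) {
  n <- length(images)
  if (model$with_exits) {
    nex <- model$config$n_exits
    probs <- lapply(seq_len(nex), function(m)
      matrix(0, n, model$config$num_classes))
    for (s in seq(1L, n, by = batch_size)) {
      idx <- s:min(s + batch_size - 1L, n)
      b <- student_forward(model, as_image_batch(images[idx], stats),
                           training = FALSE)
      for (m in seq_len(nex)) probs[[m]][idx, ] <- soften(b$logits[[m]], 1)
    }
    probs
  } else {
    p <- matrix(0, n, model$config$num_classes)
    for (s in seq(1L, n, by = batch_size)) {
      idx <- s:min(s + batch_size - 1L, n)
      p[idx, ] <- soften(
        teacher_forward(model, as_image_batch(images[idx], stats))$logits, 1)
    }
    list(p)
  }
}

augment_train_images <- function(images, policy, seed, epoch) {
  if (is.null(policy)) return(images)
  lapply(seq_along(images), function(i)
    augment(images[[i]], policy, derive_seed(seed, sprintf("aug-%d-%d", epoch, i))))
}

#' Stage 1: supervised pretraining
#'
#' Plain cross-entropy training of a single-head classifier on a (source
#' domain) dataset, with the configured SGD schedule. Returns the
#' best-validation-accuracy snapshot. Deterministic given the seed.
#'
#' @param model A `cyto_model` built with `with_exits = FALSE`.
#' @param source_set A split `cell_image_set` with an `image` column.
#' @param cfg A [distill_config()].
#' @param seed Master seed for data order and augmentation.
#' @param policy Optional [augment_policy()] applied to training images.
#' @param verbose Print per-epoch progress.
#' @return A `pretrain_fit`: list with `model` (best snapshot), `final_model`,
#'   `history` (tibble: epoch, lr, train_loss, val_accuracy), `stats`
#'   (normalization statistics used).
#' @export
pretrain <- function(model, source_set, cfg = distill_config(), seed = 1L,
                     policy = NULL, verbose = FALSE) {
  if (model$with_exits)
    abort_config("pretrain expects a plain single-head model (with_exits = FALSE)")
  if (is.null(source_set$split))
    abort_data("source_set has no split; call split_dataset() first")
  if (max(source_set$class_index) > model$config$num_classes)
    abort_config(sprintf(
      "model head has %d classes but the dataset has %d",
      model$config$num_classes, max(source_set$class_index)))
  stats <- norm_stats(source_set)
  tr <- source_set[source_set$split == "train", ]
  va <- source_set[source_set$split == "val", ]
  vel <- NULL
  best <- list(acc = -Inf, params = model$params)
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs) - 1L) {
    lr <- lr_at_epoch(cfg, ep)
    imgs <- augment_train_images(tr$image, policy,
                                 derive_seed(seed, "augment"), ep)
    batches <- epoch_batches(nrow(tr), cfg$batch_size,
                             derive_seed(seed, paste0("order-", ep)))
    ep_loss <- 0
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      x <- as_image_batch(imgs[idx], stats)
      y <- tr$class_index[idx]
      fw <- teacher_forward(model, x, training = TRUE)
      loss <- cross_entropy(soften(fw$logits, 1), y)
      if (!is.finite(loss)) abort_contract("non-finite training loss")
      g <- teacher_backward(model, fw$caches, grad_ce_logits(fw$logits, y))
      st <- sgd_step(model$params, g, vel, lr, cfg$momentum, cfg$weight_decay)
      model$params <- st$params
      vel <- st$vel
      model$params <- merge_plain_state(model$params, fw$state)
      ep_loss <- ep_loss + loss * length(idx)
    }
    ep_loss <- ep_loss / nrow(tr)
    vp <- infer_probs(model, va$image, stats)[[1]]
    vacc <- mean(max.col(vp, "first") == va$class_index)
    if (vacc > best$acc) best <- list(acc = vacc, params = model$params)
    hist[[ep + 1L]] <- tibble::tibble(epoch = ep, lr = lr,
                                      train_loss = ep_loss,
                                      val_accuracy = vacc)
    if (verbose)
      message(sprintf("epoch %3d  lr %.4g  loss %.4f  val acc %.4f",
                      ep, lr, ep_loss, vacc))
  }
  best_model <- model
  best_model$params <- best$params
  structure(list(model = best_model, final_model = model,
                 history = dplyr::bind_rows(hist), stats = stats,
                 config = cfg),
            class = "pretrain_fit")
}

merge_plain_state <- function(params, state) {
  params$stem$bn$run_mean <- state$stem_bn$run_mean
  params$stem$bn$run_var <- state$stem_bn$run_var
  for (s in seq_along(params$stages))
    params$stages[[s]] <- merge_stage_state(params$stages[[s]],
                                            state$stages[[s]])
  params
}

#' Transfer pretrained backbone weights into a student
#'
#' Copies stem and stage weights from a checkpoint (or fitted model) into the
#' target student; every class-count-dependent layer (exit heads, the plain
#' head) is freshly initialized for the target class count unless
#' `reinit_heads = FALSE` and the class counts match.
#'
#' @param student Target `cyto_model`.
#' @param checkpoint A `cyto_model`, a `pretrain_fit`, or a checkpoint path.
#' @param num_target_classes Target class count.
#' @param reinit_heads Reinitialize heads (default `TRUE`).
#' @param seed Seed for head reinitialization.
#' @return The student with transferred weights; attribute
#'   `transfer_report` lists transferred and reinitialized tensor groups.
#' @export
transfer_load <- function(student, checkpoint, num_target_classes =
                            student$config$num_classes,
                          reinit_heads = TRUE, seed = 1L) {
  src <- checkpoint
  if (is.character(src)) src <- load_checkpoint(src)
  if (inherits(src, "pretrain_fit")) src <- src$model
  sp <- src$params
  tp <- student$params
  same_backbone <- identical(dim(sp$stem$conv$W), dim(tp$stem$conv$W)) &&
    length(sp$stages) == length(tp$stages)
  if (!same_backbone)
    abort_data("no overlapping backbone tensors between checkpoint and student")
  tp$stem <- sp$stem
  transferred <- "stem"
  for (s in seq_along(tp$stages)) {
    if (length(sp$stages[[s]]) != length(tp$stages[[s]]))
      abort_data(sprintf("stage %d block count differs", s))
    tp$stages[[s]] <- sp$stages[[s]]
    transferred <- c(transferred, sprintf("stage%d", s))
  }
  reinit <- character(0)
  student$config$num_classes <- as.integer(num_target_classes)
  if (!reinit_heads) {
    if (!student$with_exits && !is.null(sp$head) &&
        ncol(sp$head$W) == num_target_classes) {
      tp$head <- sp$head
      transferred <- c(transferred, "head")
    } else if (student$with_exits && !is.null(sp$exits) &&
               ncol(sp$exits[[1]]$head$W) == num_target_classes) {
      tp$exits <- sp$exits
      transferred <- c(transferred, "exits")
    } else if (ncol((sp$head %||% sp$exits[[1]]$head)$W) != num_target_classes) {
      abort_config(
        "reinit_heads = FALSE requires matching class counts and head layout")
    }
  }
  if (reinit_heads) {
    top_w <- student$config$arch$widths[length(student$config$arch$widths)]
    if (student$with_exits) {
      with_seed(derive_seed(seed, "heads"), {
        for (m in seq_along(tp$exits)) {
          tp$exits[[m]]$head <- fc_init(top_w, num_target_classes)
          reinit <- c(reinit, sprintf("exit%d.head", m))
        }
      })
    } else {
      tp$head <- with_seed(derive_seed(seed, "heads"),
                           fc_init(top_w, num_target_classes))
      reinit <- "head"
    }
  }
  student$params <- tp
  attr(student, "transfer_report") <- list(transferred = transferred,
                                           reinitialized = reinit)
  student
}

#' Stage 2: distillation fine-tuning of the multi-exit student
#'
#' Optimizes the total multi-exit objective — per-exit knowledge distillation
#' against the frozen teacher plus self-distillation from the deepest exit —
#' with SGD over the union of backbone and exit parameters. With
#' `teacher = NULL` the run degenerates to the cross-entropy-only multi-exit
#' baseline (every exit supervised by labels alone). Model selection is by
#' best ensemble validation accuracy.
#'
#' @param student Multi-exit `cyto_model`.
#' @param teacher Frozen `cyto_model` (or `NULL` for the CE-only baseline).
#' @param target_set Split `cell_image_set` with an `image` column.
#' @param cfg A [distill_config()].
#' @param seed Master seed.
#' @param policy Optional training-time [augment_policy()].
#' @param verbose Print per-epoch progress.
#' @return A `distill_fit`: `model` (best snapshot), `final_model`, `history`
#'   (tibble: epoch, lr, train_loss, per-exit and ensemble val accuracy),
#'   `stats`, `teacher_hash` (before/after, equal by contract), `config`.
#' @export
finetune_distill <- function(student, teacher, target_set,
                             cfg = distill_config(), seed = 1L, policy = NULL,
                             verbose = FALSE) {
  if (!student$with_exits)
    abort_config("finetune_distill needs a multi-exit student")
  if (!is.null(teacher)) {
    if (!teacher$frozen)
      abort_contract("teacher is not frozen; freeze it before distillation")
    if (teacher$config$num_classes != student$config$num_classes)
      abort_config("teacher and student class counts differ")
  }
  if (is.null(target_set$split))
    abort_data("target_set has no split; call split_dataset() first")
  stats <- norm_stats(target_set)
  tr <- target_set[target_set$split == "train", ]
  va <- target_set[target_set$split == "val", ]
  nex <- student$config$n_exits
  hash_before <- if (!is.null(teacher)) object_hash(teacher$params) else NA
  vel <- NULL
  best <- list(acc = -Inf, params = student$params)
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs) - 1L) {
    lr <- lr_at_epoch(cfg, ep)
    imgs <- augment_train_images(tr$image, policy,
                                 derive_seed(seed, "augment"), ep)
    batches <- epoch_batches(nrow(tr), cfg$batch_size,
                             derive_seed(seed, paste0("order-", ep)))
    ep_loss <- 0
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      x <- as_image_batch(imgs[idx], stats)
      y <- tr$class_index[idx]
      bundle <- student_forward(student, x, training = TRUE)
      if (!is.null(teacher)) {
        t_logits <- teacher_forward(teacher, x)$logits
        g <- total_loss_grads(bundle, t_logits, y, cfg)
        loss <- g$loss
        dlogits <- g$dlogits
        dfeatures <- g$dfeatures
      } else {
        loss <- 0
        dlogits <- vector("list", nex)
        for (m in seq_len(nex)) {
          loss <- loss + cross_entropy(soften(bundle$logits[[m]], 1), y)
          dlogits[[m]] <- grad_ce_logits(bundle$logits[[m]], y)
        }
        dfeatures <- vector("list", nex)
      }
      if (!is.finite(loss)) abort_contract("non-finite training loss")
      grads <- student_backward(student, bundle, dlogits, dfeatures)
      st <- sgd_step(student$params, grads, vel, lr, cfg$momentum,
                     cfg$weight_decay)
      student$params <- st$params
      vel <- st$vel
      student <- apply_bn_state(student, bundle$state)
      ep_loss <- ep_loss + loss * length(idx)
    }
    ep_loss <- ep_loss / nrow(tr)
    probs <- infer_probs(student, va$image, stats)
    accs <- vapply(probs, function(p)
      mean(max.col(p, "first") == va$class_index), numeric(1))
    ens_acc <- mean(max.col(ensemble_predict(probs), "first") ==
                      va$class_index)
    if (ens_acc > best$acc) best <- list(acc = ens_acc,
                                         params = student$params)
    row <- tibble::tibble(epoch = ep, lr = lr, train_loss = ep_loss)
    for (m in seq_len(nex)) row[[paste0("acc_exit", m)]] <- accs[m]
    row$acc_ensemble <- ens_acc
    hist[[ep + 1L]] <- row
    if (verbose)
      message(sprintf("epoch %3d  lr %.4g  loss %.4f  ens val acc %.4f",
                      ep, lr, ep_loss, ens_acc))
  }
  hash_after <- if (!is.null(teacher)) object_hash(teacher$params) else NA
  if (!is.null(teacher) && !identical(hash_before, hash_after))
    abort_contract("teacher parameters changed during distillation")
  best_model <- student
  best_model$params <- best$params
  structure(list(model = best_model, final_model = student,
                 history = dplyr::bind_rows(hist), stats = stats,
                 teacher_hash = c(before = hash_before, after = hash_after),
                 config = cfg),
            class = "distill_fit")
}

#' Tidy training history of a fitted run
#'
#' @param x A `distill_fit` or `pretrain_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble in long form (metric, value).
#' @export
tidy.distill_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, -c("epoch", "lr"),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.distill_fit
#' @export
tidy.pretrain_fit <- tidy.distill_fit

#' One-row summary of a distillation run
#'
#' @param x A `distill_fit`.
#' @param ... Unused.
#' @return One-row tibble: epochs run, final train loss, best ensemble
#'   validation accuracy.
#' @export
glance.distill_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history),
                 final_train_loss = x$history$train_loss[nrow(x$history)],
                 best_val_accuracy = max(x$history$acc_ensemble))
}

#' @export
glance.pretrain_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history),
                 final_train_loss = x$history$train_loss[nrow(x$history)],
                 best_val_accuracy = max(x$history$val_accuracy))
}

#' Training-curve plot
#'
#' @param object A `distill_fit` or `pretrain_fit`.
#' @param ... Unused.
#' @return A ggplot of per-epoch loss and validation accuracies.
#' @export
autoplot.distill_fit <- function(object, ...) {
  d <- tidy.distill_fit(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$epoch, .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.distill_fit
#' @export
autoplot.pretrain_fit <- autoplot.distill_fit

# ---- run manifest -----------------------------------------------------------

#' Content fingerprint of a dataset
#'
#' @param dataset A `cell_image_set`.
#' @return md5 hex string over labels and image content (or file names).
#' @export
dataset_fingerprint <- function(dataset) {
  payload <- list(class_index = dataset$class_index,
                  split = as.character(dataset$split %||% ""),
                  content = if (!is.null(dataset$image)) dataset$image
                            else dataset$file)
  object_hash(payload)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the configuration echo, all
#' seeds, content fingerprints of the input datasets, and library versions.
#' The body is a pure function of its inputs (no timestamps), so identical
#' runs produce identical manifests.
#'
#' @param cfg A [distill_config()].
#' @param seeds Named list/vector of seeds used.
#' @param fingerprints Named list of dataset fingerprints
#'   ([dataset_fingerprint()]).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
run_manifest <- function(cfg, seeds, fingerprints, path) {
  body <- list(
    config = unclass(cfg),
    seeds = as.list(seeds),
    dataset_fingerprints = as.list(fingerprints),
    versions = list(r = paste(R.version$major, R.version$minor, sep = "."),
                    cytodistill = as.character(utils::packageVersion("cytodistill"))))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(body, path)
  invisible(path)
}

#' Load a training configuration from a YAML file or manifest
#'
#' Accepts either a bare configuration mapping or a manifest written by
#' [run_manifest()] (whose `config` entry is used).
#'
#' @param path YAML file path.
#' @return A [distill_config()].
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$config)) y <- y$config
  keep <- intersect(names(y), names(formals(distill_config)))
  do.call(distill_config, y[keep])
}
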
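# Ensemble inference, confusion matrices, and macro metrics.

#' Average-ensemble prediction over exit probabilities
#'
#' The final classifier is the unweighted average of the exits' probability
#' vectors: `f = (1/n) * sum_m S_m`. Rows of the result sum to 1 whenever
#' every input's rows do; the row argmax is the ensemble prediction.
#'
#' @param exit_probs List of `(batch, C)` row-normalized probability
#'   matrices, one per exit.
#' @return `(batch, C)` matrix of averaged probabilities.
#' @export
ensemble_predict <- function(exit_probs) {
  if (length(exit_probs) == 0L) abort_contract("exit_probs is empty")
  d <- dim(exit_probs[[1]])
  for (m in seq_along(exit_probs))
    if (!identical(dim(exit_probs[[m]]), d))
      abort_contract("exit probability matrices must share one shape")
  Reduce(`+`, exit_probs) / length(exit_probs)
}

#' Confusion matrix
#'
#' Entry `(i, j)` counts samples of true class i predicted as class j.
#'
#' @param predictions,labels Integer vectors in `1..C`.
#' @param C Class count.
#' @return `C x C` integer matrix; its total equals `length(labels)`.
#' @export
confusion <- function(predictions, labels, C) {
  p <- as.integer(predictions)
  y <- as.integer(labels)
  if (any(p < 1L | p > C) || any(y < 1L | y > C))
    abort_data(sprintf("class indices out of range 1..%d", C))
  m <- matrix(0L, C, C)
  for (i in seq_along(y)) m[y[i], p[i]] <- m[y[i], p[i]] + 1L
  m
}

#' Macro-averaged classification metrics from a confusion matrix
#'
#' Accuracy is trace/total. Per class: sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP), precision TP/(TP+FP), F-measure the harmonic mean of
#' precision and sensitivity. Macro values are unweighted means over classes;
#' classes with zero support are excluded from the macro mean (with a
#' warning).
#'
#' @param conf `C x C` confusion matrix (rows = true class).
#' @return A one-row tibble: `accuracy`, `sensitivity`, `specificity`,
#'   `f_measure` (all in `[0, 1]`), plus `n` evaluated samples.
#' @export
macro_metrics <- function(conf) {
  conf <- as.matrix(conf)
  total <- sum(conf)
  if (total == 0) abort_data("confusion matrix is all zero")
  C <- nrow(conf)
  tp <- diag(conf)
  fn <- rowSums(conf) - tp
  fp <- colSums(conf) - tp
  tn <- total - tp - fn - fp
  support <- rowSums(conf)
  keep <- support > 0
  if (!all(keep))
    warn(sprintf("%d class(es) with zero support excluded from macro means",
                 sum(!keep)))
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  f <- ifelse(prec + sens > 0, 2 * prec * sens / (prec + sens), 0)
  tibble::tibble(
    accuracy = sum(tp) / total,
    sensitivity = mean(sens[keep]),
    specificity = mean(spec[keep]),
    f_measure = mean(f[keep]),
    n = total)
}

#' Evaluate a multi-exit model on a labeled dataset
#'
#' Runs inference (temperature-1 softmax at every exit), forms the average
#' ensemble, and assembles per-exit and ensemble confusion matrices and
#' macro metrics.
#'
#' @param model A `cyto_model` student.
#' @param dataset A `cell_image_set` with an `image` column (typically one
#'   split).
#' @param stats Normalization statistics from [norm_stats()] (or `NULL`).
#' @param batch_size Inference batch size.
#' @return A `metrics_report` object: list with `per_exit` (list of
#'   confusion matrices), `ensemble` (confusion matrix), `exit_metrics`
#'   (tibble, one row per exit + ensemble), `class_names`, `n_exits`.
#' @export
evaluate_model <- function(model, dataset, stats = NULL, batch_size = 64L) {
  n <- nrow(dataset)
  nex <- model$config$n_exits
  C <- model$config$num_classes
  probs <- lapply(seq_len(nex), function(m) matrix(0, n, C))
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, n)
    x <- as_image_batch(dataset$image[idx], stats)
    b <- student_forward(model, x, training = FALSE)
    for (m in seq_len(nex)) probs[[m]][idx, ] <- soften(b$logits[[m]], 1)
  }
  ens <- ensemble_predict(probs)
  labels <- dataset$class_index
  per_exit <- lapply(probs, function(p) confusion(max.col(p, "first"), labels, C))
  ens_conf <- confusion(max.col(ens, "first"), labels, C)
  mk <- function(conf, name) dplyr::mutate(macro_metrics(conf), exit = name,
                                           .before = 1)
  exit_metrics <- dplyr::bind_rows(
    c(lapply(seq_len(nex), function(m) mk(per_exit[[m]], paste0("exit_", m))),
      list(mk(ens_conf, "ensemble"))))
  structure(list(per_exit = per_exit, ensemble = ens_conf,
                 exit_metrics = exit_metrics,
                 class_names = attr(dataset, "class_names") %||%
                   sort(unique(dataset$class_name)),
                 n_exits = nex),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Multi-exit evaluation (", sum(x$ensemble), " samples, ",
      x$n_exits, " exits)\n", sep = "")
  print(dplyr::mutate(x$exit_metrics,
                      dplyr::across(dplyr::where(is.double), ~ round(.x, 4))))
  invisible(x)
}

#' Tidy a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Long tibble with columns `exit`, `metric`, `value`.
#' @export
tidy.metrics_report <- function(x, ...) {
  tidyr::pivot_longer(x$exit_metrics,
                      c("accuracy", "sensitivity", "specificity", "f_measure"),
                      names_to = "metric", values_to = "value")
}

#' One-row summary of a metrics report (the ensemble row)
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return One-row tibble of ensemble macro metrics.
#' @export
glance.metrics_report <- function(x, ...) {
  dplyr::filter(x$exit_metrics, .data$exit == "ensemble")
}

#' Confusion heatmaps for every exit and the ensemble
#'
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot faceted by exit.
#' @export
autoplot.metrics_report <- function(object, ...) {
  cn <- object$class_names
  fmt <- function(conf, name) {
    df <- as.data.frame(as.table(conf))
    names(df) <- c("true", "predicted", "count")
    levels(df$true) <- cn
    levels(df$predicted) <- cn
    df$exit <- name
    df
  }
  d <- dplyr::bind_rows(c(
    lapply(seq_along(object$per_exit),
           function(m) fmt(object$per_exit[[m]], paste0("exit_", m))),
    list(fmt(object$ensemble, "ensemble"))))
  ggplot2::ggplot(d, ggplot2::aes(.data$predicted, .data$true,
                                  fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7bb6") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::facet_wrap(~exit) +
    ggplot2::labs(x = "predicted class", y = "true class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  }

#' Write a metrics report to disk
#'
#' Writes the metrics table as CSV, each confusion matrix as CSV, and the
#' confusion heatmap as PNG.
#'
#' @param report A `metrics_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$exit_metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  dimnames(report$ensemble) <- list(report$class_names, report$class_names)
  utils::write.csv(report$ensemble, file.path(dir, "confusion_ensemble.csv"))
  for (m in seq_along(report$per_exit)) {
    cm <- report$per_exit[[m]]
    dimnames(cm) <- list(report$class_names, report$class_names)
    utils::write.csv(cm, file.path(dir, sprintf("confusion_exit%d.csv", m)))
  }
  p <- autoplot.metrics_report(report)
  ggplot2::ggsave(file.path(dir, "confusion.png"), p, width = 8, height = 6,
                  dpi = 120)
  invisible(dir)
}
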
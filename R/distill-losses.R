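# Loss functions of the distillation objective.
#
# Notation: S_m are the raw logits of exit m (S_n the deepest exit), t the
# teacher's temperature-softened distribution, y the labels, tau the
# distillation temperature, lambda the feature-loss weight. All losses are
# means over the batch; log arguments are clamped at 1e-12.

LOG_EPS <- 1e-12

#' Distillation training configuration
#'
#' All training hyperparameters of the two-stage procedure, with the study's
#' defaults: 180 epochs, batch size 128, SGD with initial learning rate 0.1
#' decayed by 0.1 at epochs 100 and 150, weight decay 1e-4, momentum 0.9,
#' temperature tau = 3 and feature-loss weight lambda = 0.03.
#'
#' @param tau Distillation temperature (> 0). Shared by the teacher- and
#'   student-side softening.
#' @param lam Weight of the feature mean-squared term in the
#'   self-distillation loss.
#' @param kl_direction `"student_to_teacher"` (default; the softened student
#'   distribution occupies the log numerator, i.e. forward KL from the
#'   student) or `"teacher_to_student"` (the conventional distillation
#'   direction).
#' @param dedup_deep_ce The total objective sums, over all n exits, a
#'   per-exit term that each contains the deep exit's cross-entropy. With
#'   `FALSE` (default) that cross-entropy is counted once per exit, following
#'   the summation as printed; with `TRUE` it is counted once overall (the
#'   two differ by exactly `(n-1) * CE(S_n, y)`).
#' @param epochs,batch_size,lr,lr_milestones,lr_gamma,weight_decay,momentum
#'   SGD schedule parameters.
#' @return A `distill_config` list.
#' @export
distill_config <- function(tau = 3, lam = 0.03,
                           kl_direction = "student_to_teacher",
                           dedup_deep_ce = FALSE,
                           epochs = 180L, batch_size = 128L, lr = 0.1,
                           lr_milestones = c(100L, 150L), lr_gamma = 0.1,
                           weight_decay = 1e-4, momentum = 0.9) {
  if (tau <= 0) abort_config("tau must be > 0")
  if (lam < 0) abort_config("lam must be >= 0")
  if (!kl_direction %in% c("student_to_teacher", "teacher_to_student"))
    abort_config("kl_direction must be 'student_to_teacher' or 'teacher_to_student'")
  structure(list(tau = tau, lam = lam, kl_direction = kl_direction,
                 dedup_deep_ce = isTRUE(dedup_deep_ce),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, lr_milestones = as.integer(lr_milestones),
                 lr_gamma = lr_gamma, weight_decay = weight_decay,
                 momentum = momentum),
            class = "distill_config")
}

#' Cross-entropy of predicted probabilities against integer labels
#'
#' Mean over samples of `-log p[i, y_i]`. Probabilities at the true class are
#' clamped below at 1e-12 (a clamp event raises a warning).
#'
#' @param predicted_probs `(n, m)` matrix, rows summing to 1.
#' @param true_labels Integer vector in `1..m` (length n).
#' @return Scalar loss.
#' @export
cross_entropy <- function(predicted_probs, true_labels) {
  p <- as.matrix(predicted_probs)
  y <- as.integer(true_labels)
  if (any(y < 1L) || any(y > ncol(p)))
    abort_contract("labels out of range 1..m")
  if (length(y) != nrow(p))
    abort_contract("length(true_labels) must equal nrow(predicted_probs)")
  py <- p[cbind(seq_len(nrow(p)), y)]
  if (any(py < LOG_EPS))
    warn("zero predicted probability at the true class; clamped at 1e-12")
  -mean(log(pmax(py, LOG_EPS)))
}

#' Temperature-scaled softmax
#'
#' `t_k = exp(z_k / tau) / sum_k exp(z_k / tau)`, computed row-wise with a
#' max-shift for numerical stability. `tau = 1` is the ordinary softmax;
#' larger tau flattens the distribution towards uniform.
#'
#' @param logits `(n, C)` matrix of raw scores.
#' @param tau Temperature (> 0).
#' @return `(n, C)` matrix of probabilities; rows sum to 1.
#' @export
soften <- function(logits, tau = 1) {
  if (tau <= 0) abort_config("tau must be > 0")
  softmax_rows(as.matrix(logits) / tau)
}

# KL divergence sum_k p_k log(p_k / q_k) between probability rows, mean over
# rows.
kl_rows <- function(p, q) {
  p <- pmax(p, LOG_EPS)
  q <- pmax(q, LOG_EPS)
  mean(rowSums(p * (log(p) - log(q))))
}

#' Temperature-softened KL distillation divergence
#'
#' Softens both logit sets at temperature `tau` and returns the mean
#' row-wise KL divergence. Direction `"student_to_teacher"` puts the
#' student's softened distribution in the log numerator (forward KL from the
#' student, the printed form of the objective); `"teacher_to_student"` is
#' the conventional distillation direction.
#'
#' @param student_logits,teacher_logits `(n, C)` matrices of equal shape.
#' @param tau Temperature.
#' @param direction KL direction, see above.
#' @return Scalar divergence (>= 0).
#' @export
kl_distill <- function(student_logits, teacher_logits, tau = 1,
                       direction = "student_to_teacher") {
  if (!identical(dim(as.matrix(student_logits)), dim(as.matrix(teacher_logits))))
    abort_contract("student and teacher logits must have identical shapes")
  p <- soften(student_logits, tau)
  q <- soften(teacher_logits, tau)
  switch(direction,
    student_to_teacher = kl_rows(p, q),
    teacher_to_student = kl_rows(q, p),
    abort_config(sprintf("unknown kl direction '%s'", direction)))
}

#' Per-exit knowledge distillation loss
#'
#' The regular knowledge-distillation term for exit m:
#' `tau^2 * KL(S_m, t) + CE(softmax(S_m), y) + CE(softmax(S_n), y)`,
#' where `t` is the teacher's softened distribution (already at `cfg$tau`),
#' and tau^2 rescales only the KL term so its gradient magnitude is
#' temperature-independent.
#'
#' @param S_m Exit-m logits `(n, C)`.
#' @param teacher_soft Teacher softened probabilities `(n, C)` (from
#'   [soften()] at `cfg$tau`).
#' @param labels Integer labels in `1..C`.
#' @param S_n Deepest-exit logits `(n, C)`.
#' @param cfg A [distill_config()].
#' @return Scalar loss.
#' @export
exit_kd_loss <- function(S_m, teacher_soft, labels, S_n, cfg = distill_config()) {
  p <- soften(S_m, cfg$tau)
  kl <- switch(cfg$kl_direction,
    student_to_teacher = kl_rows(p, teacher_soft),
    teacher_to_student = kl_rows(teacher_soft, p))
  cfg$tau^2 * kl + cross_entropy(soften(S_m, 1), labels) +
    cross_entropy(soften(S_n, 1), labels)
}

#' Per-exit self-distillation loss
#'
#' The deepest exit acts as an internal teacher for exit m:
#' `tau^2 * KL(S_m, S_n) + lam * MSE(mu_m(F_m), F_n)`, with the mean squared
#' error averaged over all feature elements. `S_n` and `F_n` are treated as
#' constants (no gradient reaches the deepest exit through this loss during
#' training).
#'
#' @param S_m,S_n Exit logits `(n, C)`.
#' @param F_m_unified Exit-m feature map after its scale-unifying bottleneck.
#' @param F_n Deepest-exit feature map (same shape).
#' @param cfg A [distill_config()].
#' @param m Exit index, used only in error messages.
#' @return Scalar loss.
#' @export
self_distill_loss <- function(S_m, S_n, F_m_unified, F_n,
                              cfg = distill_config(), m = NA_integer_) {
  if (!identical(dim(F_m_unified), dim(F_n)))
    abort_contract(sprintf(
      "unified feature shape of exit %s does not match the deepest exit's",
      m))
  kl <- switch(cfg$kl_direction,
    student_to_teacher = kl_rows(soften(S_m, cfg$tau), soften(S_n, cfg$tau)),
    teacher_to_student = kl_rows(soften(S_n, cfg$tau), soften(S_m, cfg$tau)))
  cfg$tau^2 * kl + cfg$lam * mean((F_m_unified - F_n)^2)
}

#' Total multi-exit distillation objective
#'
#' Sums the per-exit knowledge-distillation and self-distillation losses over
#' all n exits. The self-distillation term vanishes at the deepest exit. With
#' `cfg$dedup_deep_ce` the deep exit's cross-entropy inside the KD term is
#' counted once overall instead of once per exit.
#'
#' @param bundle An `exit_bundle` from [student_forward()].
#' @param teacher_logits Frozen-teacher logits `(n, C)`.
#' @param labels Integer labels in `1..C`.
#' @param cfg A [distill_config()].
#' @return List with `total` (scalar) and `breakdown`, a tibble with one row
#'   per exit and columns `kd_kl`, `ce_m`, `ce_n`, `sd_kl`, `sd_feat`.
#' @export
total_loss <- function(bundle, teacher_logits, labels, cfg = distill_config()) {
  n <- bundle$n
  if (n < 2L) abort_contract("total_loss needs a bundle with >= 2 exits")
  t_soft <- soften(teacher_logits, cfg$tau)
  S_n <- bundle$logits[[n]]
  F_n <- bundle$features[[n]]
  ce_n <- cross_entropy(soften(S_n, 1), labels)
  rows <- vector("list", n)
  total <- 0
  for (m in seq_len(n)) {
    S_m <- bundle$logits[[m]]
    p_m <- soften(S_m, cfg$tau)
    kd_kl <- switch(cfg$kl_direction,
      student_to_teacher = kl_rows(p_m, t_soft),
      teacher_to_student = kl_rows(t_soft, p_m))
    ce_m <- cross_entropy(soften(S_m, 1), labels)
    deep_ce <- if (cfg$dedup_deep_ce && m != n) 0 else ce_n
    if (m < n) {
      sd_kl <- switch(cfg$kl_direction,
        student_to_teacher = kl_rows(p_m, soften(S_n, cfg$tau)),
        teacher_to_student = kl_rows(soften(S_n, cfg$tau), p_m))
      sd_feat <- mean((bundle$features[[m]] - F_n)^2)
    } else {
      sd_kl <- 0
      sd_feat <- 0
    }
    term <- cfg$tau^2 * kd_kl + ce_m + deep_ce +
      cfg$tau^2 * sd_kl + cfg$lam * sd_feat
    total <- total + term
    rows[[m]] <- tibble::tibble(
      exit = m, kd_kl = kd_kl, ce_m = ce_m, ce_n = deep_ce,
      sd_kl = sd_kl, sd_feat = sd_feat, term = term)
  }
  list(total = total, breakdown = dplyr::bind_rows(rows))
}

# ---- analytic gradients of the total objective ------------------------------
#
# Used by the training loop. Stop-gradient convention: no gradient reaches
# S_n or F_n through the self-distillation terms of shallower exits; S_n
# still receives gradient from its own KD term and from the deep
# cross-entropy copies.

# d/dz of mean-over-rows CE(softmax(z), y): (softmax(z) - onehot)/n.
grad_ce_logits <- function(z, labels) {
  p <- softmax_rows(z)
  n <- nrow(z)
  p[cbind(seq_len(n), labels)] <- p[cbind(seq_len(n), labels)] - 1
  p / n
}

# d/dz_s of mean-row KL at temperature tau (z_t fixed), both directions.
grad_kl_student <- function(z_s, q_soft, tau, direction) {
  p <- soften(z_s, tau)
  n <- nrow(z_s)
  if (direction == "student_to_teacher") {
    lr_ <- log(pmax(p, LOG_EPS)) - log(pmax(q_soft, LOG_EPS))
    g <- p * (lr_ - rowSums(p * lr_))
  } else {
    g <- p - q_soft
  }
  g / (tau * n)
}

# Gradients of the total objective wrt every exit's logits and unified
# features. Returns list(dlogits = list, dfeatures = list, loss, breakdown).
total_loss_grads <- function(bundle, teacher_logits, labels, cfg) {
  n <- bundle$n
  t_soft <- soften(teacher_logits, cfg$tau)
  S_n <- bundle$logits[[n]]
  Sn_soft <- soften(S_n, cfg$tau)
  F_n <- bundle$features[[n]]
  nel <- length(F_n)
  dlogits <- vector("list", n)
  dfeatures <- vector("list", n)
  for (m in seq_len(n)) {
    S_m <- bundle$logits[[m]]
    g <- cfg$tau^2 * grad_kl_student(S_m, t_soft, cfg$tau, cfg$kl_direction) +
      grad_ce_logits(S_m, labels)
    if (m < n) {
      g <- g + cfg$tau^2 *
        grad_kl_student(S_m, Sn_soft, cfg$tau, cfg$kl_direction)
      dfeatures[[m]] <- 2 * cfg$lam * (bundle$features[[m]] - F_n) / nel
    }
    dlogits[[m]] <- g
  }
  # deep CE copies: once per exit (literal) or once overall (dedup), plus the
  # m = n term's own CE which is already in dlogits[[n]]
  n_copies <- if (cfg$dedup_deep_ce) 1 else n
  dlogits[[n]] <- dlogits[[n]] + n_copies * grad_ce_logits(S_n, labels)
  lb <- total_loss(bundle, teacher_logits, labels, cfg)
  list(dlogits = dlogits, dfeatures = dfeatures,
       loss = lb$total, breakdown = lb$breakdown)
}
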
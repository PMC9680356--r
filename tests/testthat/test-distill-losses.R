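test_that("cross-entropy matches closed forms and hand arithmetic", {
  onehot <- diag(3)[c(1, 2, 3), ]
  expect_equal(cross_entropy(pmin(onehot + 1e-15, 1), c(1, 2, 3)), 0,
               tolerance = 1e-10)
  unif <- matrix(1 / 4, 5, 4)
  expect_equal(cross_entropy(unif, c(1, 2, 3, 4, 1)), log(4),
               tolerance = 1e-12)
  p <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1))
  expect_equal(cross_entropy(p, c(1, 2)), -0.5 * (log(0.7) + log(0.8)),
               tolerance = 1e-12)
  expect_equal(cross_entropy(p, c(1, 2)), oracle_ce(p, c(1, 2)),
               tolerance = 1e-12)
  expect_error(cross_entropy(p, c(1, 4)), "range")
  expect_warning(cross_entropy(rbind(c(0, 1), c(1, 0)), c(1, 2)), "clamped")
})

test_that("temperature softmax obeys its limits and hand values", {
  set.seed(31)
  z <- matrix(rnorm(12, sd = 3), 3, 4)
  expect_equal(soften(z, 1), t(apply(z, 1, oracle_soften_row, tau = 1)),
               tolerance = 1e-12)
  expect_equal(rowSums(soften(z, 3)), rep(1, 3), tolerance = 1e-12)
  # tau -> infinity flattens to uniform
  expect_lt(max(abs(soften(z, 1e6) - 1 / 4)), 1e-5)
  # printed example: logits (0, log 4) at tau = 2 soften to (1/3, 2/3)
  expect_equal(as.numeric(soften(matrix(c(0, log(4)), 1), 2)), c(1, 2) / 3,
               tolerance = 1e-12)
  expect_error(soften(z, 0), "tau")
  # entropy is non-decreasing in tau
  ent <- function(p) -sum(p * log(p))
  taus <- c(0.25, 0.5, 1, 2, 3, 5, 10, 100)
  for (i in 1:3) {
    e <- vapply(taus, function(tt) ent(soften(z, tt)[i, ]), numeric(1))
    expect_true(all(diff(e) >= -1e-12))
  }
})

test_that("kl divergence: zero at equality, non-negative, hand value, both directions", {
  set.seed(32)
  z <- matrix(rnorm(8), 2, 4)
  expect_equal(kl_distill(z, z, tau = 3), 0, tolerance = 1e-12)
  expect_equal(kl_distill(z, z, tau = 3, direction = "teacher_to_student"), 0,
               tolerance = 1e-12)
  for (i in 1:100) {
    zs <- matrix(rnorm(8, sd = 2), 2, 4)
    zt <- matrix(rnorm(8, sd = 2), 2, 4)
    expect_gte(kl_distill(zs, zt, tau = 2), 0)
    expect_gte(kl_distill(zs, zt, tau = 2, direction = "teacher_to_student"), 0)
  }
  # hand case: softened distributions (0.5, 0.5) vs (0.9, 0.1) at tau = 1
  zs <- matrix(log(c(0.5, 0.5)), 1)
  zt <- matrix(log(c(0.9, 0.1)), 1)
  expect_equal(kl_distill(zs, zt, tau = 1),
               0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1), tolerance = 1e-12)
  expect_equal(kl_distill(zs, zt, tau = 2), oracle_kl(zs, zt, 2),
               tolerance = 1e-12)
  expect_error(kl_distill(zs, matrix(0, 2, 2), 1), "shape")
})

test_that("per-exit kd loss decomposes into its printed components", {
  set.seed(33)
  cfg <- distill_config(tau = 3)
  S_m <- matrix(rnorm(6, sd = 2), 2, 3)
  S_n <- matrix(rnorm(6, sd = 2), 2, 3)
  zt <- matrix(rnorm(6, sd = 2), 2, 3)
  t_soft <- soften(zt, cfg$tau)
  y <- c(2L, 3L)
  got <- exit_kd_loss(S_m, t_soft, y, S_n, cfg)
  want <- cfg$tau^2 * kl_distill(S_m, zt, cfg$tau) +
    cross_entropy(soften(S_m, 1), y) + cross_entropy(soften(S_n, 1), y)
  expect_equal(got, want, tolerance = 1e-9)
  # scalar re-implementation on fixed 2-class toys at tau = 3
  S2 <- matrix(c(1, -1, 0.5, 2), 2, 2)
  T2 <- matrix(c(2, 0, 0, 1), 2, 2)
  y2 <- c(1L, 2L)
  got2 <- exit_kd_loss(S2, soften(T2, 3), y2, S2, distill_config(tau = 3))
  want2 <- 9 * oracle_kl(S2, T2, 3) +
    2 * oracle_ce(t(apply(S2, 1, oracle_soften_row, tau = 1)), y2)
  expect_equal(got2, want2, tolerance = 1e-9)
  # aligned case: student = deep = teacher logits, confident and correct
  big <- matrix(c(20, 0, 0, 20), 2, 2)
  yb <- c(1L, 2L)
  al <- exit_kd_loss(big, soften(big, 1), yb, big, distill_config(tau = 1))
  expect_equal(al, 2 * cross_entropy(soften(big, 1), yb), tolerance = 1e-6)
})

test_that("self-distillation loss: self case, ablation, constant-offset oracle", {
  set.seed(34)
  cfg <- distill_config(tau = 3, lam = 0.03)
  S_n <- matrix(rnorm(6), 2, 3)
  F_n <- array(rnorm(2 * 2 * 4 * 2), c(2, 2, 4, 2))
  expect_equal(self_distill_loss(S_n, S_n, F_n, F_n, cfg), 0,
               tolerance = 1e-12)
  S_m <- matrix(rnorm(6), 2, 3)
  F_m <- F_n + array(rnorm(length(F_n)), dim(F_n))
  cfg0 <- distill_config(tau = 3, lam = 0)
  expect_equal(self_distill_loss(S_m, S_n, F_m, F_n, cfg0),
               9 * kl_distill(S_m, S_n, 3), tolerance = 1e-12)
  # features differing by a constant c contribute exactly lam * c^2
  cc <- 0.37
  expect_equal(self_distill_loss(S_n, S_n, F_n + cc, F_n, cfg),
               cfg$lam * cc^2, tolerance = 1e-12)
  expect_error(self_distill_loss(S_m, S_n, F_m[, , , 1, drop = FALSE], F_n,
                                 cfg, m = 2),
               "exit 2")
})

test_that("the total objective equals the sum of separately computed terms", {
  set.seed(35)
  n <- 3L
  logits <- lapply(1:n, function(i) matrix(rnorm(8, sd = 2), 2, 4))
  feats <- lapply(1:n, function(i) array(rnorm(3 * 2 * 2 * 2), c(3, 2, 2, 2)))
  tl <- matrix(rnorm(8, sd = 2), 2, 4)
  y <- c(1L, 4L)
  b <- fake_bundle(logits, feats)
  cfg <- distill_config(tau = 3, lam = 0.03)
  got <- total_loss(b, tl, y, cfg)
  t_soft <- soften(tl, cfg$tau)
  want <- 0
  for (m in 1:n) {
    want <- want + exit_kd_loss(logits[[m]], t_soft, y, logits[[n]], cfg)
    if (m < n)
      want <- want + self_distill_loss(logits[[m]], logits[[n]], feats[[m]],
                                       feats[[n]], cfg)
  }
  expect_equal(got$total, want, tolerance = 1e-9)
  expect_equal(nrow(got$breakdown), n)
  expect_equal(sum(got$breakdown$term), got$total, tolerance = 1e-9)
  # independent end-to-end scalar oracle
  expect_equal(got$total,
               oracle_total_loss(logits, feats, tl, y, 3, 0.03),
               tolerance = 1e-9)
  # dedup mode differs by exactly (n - 1) deep cross-entropies
  cfg_d <- distill_config(tau = 3, lam = 0.03, dedup_deep_ce = TRUE)
  got_d <- total_loss(b, tl, y, cfg_d)
  ce_n <- cross_entropy(soften(logits[[n]], 1), y)
  expect_equal(got$total - got_d$total, (n - 1) * ce_n, tolerance = 1e-9)
})

test_that("losses are finite and invariant to per-sample logit shifts", {
  set.seed(36)
  logits <- lapply(1:2, function(i) matrix(rnorm(6, sd = 5), 2, 3))
  feats <- lapply(1:2, function(i) array(rnorm(8), c(2, 2, 1, 2)))
  tl <- matrix(rnorm(6, sd = 5), 2, 3)
  y <- c(3L, 1L)
  cfg <- distill_config()
  base <- total_loss(fake_bundle(logits, feats), tl, y, cfg)$total
  expect_true(is.finite(base))
  shifted <- lapply(logits, function(z) z + c(17, -23))
  tls <- tl + c(5, -9)
  expect_equal(total_loss(fake_bundle(shifted, feats), tls, y, cfg)$total,
               base, tolerance = 1e-9)
})

test_that("analytic loss gradients match stop-gradient-aware finite differences", {
  set.seed(37)
  n <- 3L
  logits <- lapply(1:n, function(i) matrix(rnorm(8), 2, 4))
  feats <- lapply(1:n, function(i) array(rnorm(8), c(2, 2, 1, 2)))
  tl <- matrix(rnorm(8), 2, 4)
  y <- c(2L, 4L)
  for (dir in c("student_to_teacher", "teacher_to_student")) {
    cfg <- distill_config(tau = 2, lam = 0.05, kl_direction = dir)
    g <- cytodistill:::total_loss_grads(fake_bundle(logits, feats), tl, y, cfg)
    # shallow-exit logits: full derivative
    for (m in 1:(n - 1)) {
      gn <- num_grad(function(v) {
        L <- logits; L[[m]] <- matrix(v, 2)
        total_loss(fake_bundle(L, feats), tl, y, cfg)$total
      }, logits[[m]], eps = 1e-6)
      expect_equal(g$dlogits[[m]], matrix(gn, 2), tolerance = 1e-5)
      gf <- num_grad(function(v) {
        FF <- feats; FF[[m]] <- array(v, dim(feats[[m]]))
        total_loss(fake_bundle(logits, FF), tl, y, cfg)$total
      }, feats[[m]], eps = 1e-6)
      expect_equal(g$dfeatures[[m]], array(gf, dim(feats[[m]])),
                   tolerance = 1e-5)
    }
    # gradients never reach the teacher logits, and the deepest exit gets no
    # gradient through the self-distillation terms (stop-gradient); its
    # analytic gradient equals the finite difference of the objective with
    # the self-distillation targets held fixed
    frozen_obj <- function(v) {
      L <- logits; L[[n]] <- matrix(v, 2)
      base <- total_loss(fake_bundle(L, feats), tl, y, cfg)$total
      for (m in 1:(n - 1)) {
        live <- kl_distill(logits[[m]], L[[n]], cfg$tau, cfg$kl_direction)
        fixd <- kl_distill(logits[[m]], logits[[n]], cfg$tau,
                           cfg$kl_direction)
        base <- base + cfg$tau^2 * (fixd - live)
      }
      base
    }
    gn <- num_grad(frozen_obj, logits[[n]], eps = 1e-6)
    expect_equal(g$dlogits[[n]], matrix(gn, 2), tolerance = 1e-5)
  }
})
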
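# Independent oracle implementations used across tests. These deliberately
# share no code with the package internals: plain nested loops and scalar
# arithmetic only.

# direct nested-loop 2d convolution on a channel-first (C, H, W, N) array;
# weights as the package stores them: (k*k*C_in, C_out), rows ordered channel
# fastest within kernel offset (ki, kj), offset index (kj-1)*k + ki
naive_conv <- function(x, W, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  d <- dim(x)
  C <- d[1]; H <- d[2]; Wd <- d[3]; N <- d[4]
  out_c <- ncol(W)
  oh <- (H + 2 * pad - k) %/% stride + 1L
  ow <- (Wd + 2 * pad - k) %/% stride + 1L
  xp <- array(0, c(C, H + 2 * pad, Wd + 2 * pad, N))
  xp[, pad + seq_len(H), pad + seq_len(Wd), ] <- x
  y <- array(0, c(out_c, oh, ow, N))
  for (n in seq_len(N)) for (oc in seq_len(out_c))
    for (i in seq_len(oh)) for (j in seq_len(ow)) {
      acc <- 0
      for (kj in seq_len(k)) for (ki in seq_len(k)) for (c in seq_len(C)) {
        row <- ((kj - 1L) * k + (ki - 1L)) * C + c
        acc <- acc + W[row, oc] *
          xp[c, (i - 1L) * stride + ki, (j - 1L) * stride + kj, n]
      }
      y[oc, i, j, n] <- acc
    }
  y
}

# scalar cross-entropy: mean over samples of -log p at the true class
oracle_ce <- function(probs, labels) {
  s <- 0
  for (i in seq_along(labels)) s <- s - log(probs[i, labels[i]])
  s / length(labels)
}

# scalar temperature softmax of one logit vector
oracle_soften_row <- function(z, tau) {
  e <- exp(z / tau)
  e / sum(e)
}

# scalar KL(p || q) averaged over rows of two logit matrices at temperature
# tau; `flip` swaps the roles (teacher-to-student direction)
oracle_kl <- function(zs, zt, tau, flip = FALSE) {
  tot <- 0
  for (i in seq_len(nrow(zs))) {
    p <- oracle_soften_row(zs[i, ], tau)
    q <- oracle_soften_row(zt[i, ], tau)
    if (flip) { tmp <- p; p <- q; q <- tmp }
    tot <- tot + sum(p * (log(p) - log(q)))
  }
  tot / nrow(zs)
}

# scalar re-implementation of the full multi-exit objective (literal
# summation; student-to-teacher KL; stop-gradient is irrelevant for values)
oracle_total_loss <- function(logits, features, teacher_logits, labels, tau,
                              lam, dedup = FALSE) {
  n <- length(logits)
  tot <- 0
  ce_n <- oracle_ce(t(apply(logits[[n]], 1, oracle_soften_row, tau = 1)),
                    labels)
  for (m in seq_len(n)) {
    probs_m <- t(apply(logits[[m]], 1, oracle_soften_row, tau = 1))
    tot <- tot + tau^2 * oracle_kl(logits[[m]], teacher_logits, tau) +
      oracle_ce(probs_m, labels)
    tot <- tot + if (dedup && m != n) 0 else ce_n
    if (m < n) {
      tot <- tot + tau^2 * oracle_kl(logits[[m]], logits[[n]], tau) +
        lam * mean((features[[m]] - features[[n]])^2)
    }
  }
  tot
}

# central finite difference of a scalar function at x
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + eps
    xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small synthetic dataset for fast tests
tiny_dataset <- function(n_per_class = 6, image_size = 32, seed = 7) {
  ds <- generate_dataset(synthetic_spec(image_size = image_size),
                         n_per_class = n_per_class, seed = seed)
  split_dataset(ds, seed = seed)
}

# fake exit bundle from raw matrices/arrays
fake_bundle <- function(logits, features) {
  structure(list(logits = logits, features = features, n = length(logits),
                 C = ncol(logits[[1]])), class = "exit_bundle")
}
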
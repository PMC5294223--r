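# Independent oracles used to cross-check the implementation, coded
# deliberately differently from the package internals.

# Brute-force plug-in MI: build the contingency table with explicit loops
# over every sample and every symbol cell, no shared code with
# mi_from_samples().
oracle_mi <- function(xs, ys, B, log_base = 2) {
  stopifnot(length(xs) == length(ys))
  N <- length(xs)
  joint <- matrix(0, B, B)
  for (i in seq_len(N)) {
    joint[xs[i] + 1, ys[i] + 1] <- joint[xs[i] + 1, ys[i] + 1] + 1
  }
  px <- numeric(B); py <- numeric(B)
  for (a in seq_len(B)) {
    for (b in seq_len(B)) {
      px[a] <- px[a] + joint[a, b]
      py[b] <- py[b] + joint[a, b]
    }
  }
  mi <- 0
  for (a in seq_len(B)) {
    for (b in seq_len(B)) {
      if (joint[a, b] > 0) {
        pab <- joint[a, b] / N
        mi <- mi + pab * log(pab / ((px[a] / N) * (py[b] / N)), base = log_base)
      }
    }
  }
  mi
}

# Lag alignment done independently: loop over series and positions.
oracle_lagged_mi <- function(x_mat, y_mat, k, B, log_base = 2) {
  xs <- integer(0); ys <- integer(0)
  for (s in seq_len(nrow(x_mat))) {
    for (i in seq_len(ncol(x_mat) - k)) {
      xs <- c(xs, x_mat[s, i])
      ys <- c(ys, y_mat[s, i + k])
    }
  }
  oracle_mi(xs, ys, B, log_base)
}

# Textbook pooled-variance two-sample t statistic.
oracle_t_statistic <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments of the ranked absolute differences (no ties, no zeros).
oracle_signed_rank_p <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)), length(d) <= 12)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  vs <- vapply(seq_len(2^n) - 1, function(mask) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    sum(r[signs])
  }, numeric(1))
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}
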
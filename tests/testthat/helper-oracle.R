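# Independent reference implementations used as oracles.  These are coded
# from the textbook recurrences, deliberately not sharing code with the
# package internals.

# Two-block iterative NIPALS PLS (works for univariate y as the PLS1
# special case): alternate weight/score/loading updates until the score
# vector converges, then deflate both blocks.
oracle_nipals <- function(X, y, A) {
  E <- as.matrix(X)
  Fm <- matrix(y - mean(y), ncol = 1)
  W <- NULL; P <- NULL; Q <- numeric(0)
  for (a in seq_len(A)) {
    u <- Fm[, 1]
    t_old <- rep(Inf, nrow(E))
    repeat {
      w <- drop(t(E) %*% u) / sum(u^2)
      w <- w / sqrt(sum(w^2))
      t_new <- drop(E %*% w)
      q <- drop(t(Fm) %*% t_new) / sum(t_new^2)
      u <- drop(Fm %*% q) / sum(q^2)
      if (sum((t_new - t_old)^2) / max(sum(t_new^2), 1e-300) < 1e-24) break
      t_old <- t_new
    }
    t_a <- drop(E %*% w)
    p <- drop(t(E) %*% t_a) / sum(t_a^2)
    q <- drop(t(Fm) %*% t_a) / sum(t_a^2)
    E <- E - outer(t_a, p)
    Fm <- Fm - t_a %*% t(q)
    W <- cbind(W, w); P <- cbind(P, p); Q <- c(Q, q)
  }
  b <- W %*% solve(t(P) %*% W) %*% Q
  list(b = drop(b), y_mean = mean(y))
}

# Direct evaluation of the VIP formula from a model's components.
oracle_vip <- function(W, ssy) {
  J <- nrow(W)
  vapply(seq_len(J), function(j) {
    num <- 0
    for (a in seq_len(ncol(W)))
      num <- num + ssy[a] * (W[j, a] / sqrt(sum(W[, a]^2)))^2
    sqrt(J * num / sum(ssy))
  }, numeric(1))
}

# F statistic for two groups via the pooled-variance t statistic.
oracle_f_from_t <- function(a, b) {
  unname(stats::t.test(a, b, var.equal = TRUE)$statistic^2)
}
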
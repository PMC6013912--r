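# Independent brute-force oracles, kept deliberately naive: full enumeration
# or resampling, never the package's own code paths.

# P(rank-sum of group a >= / <= observed) by enumerating every assignment of
# the pooled midranks to a group of size |a|.
oracle_rank_sum_p <- function(a, b, alternative = "greater") {
  r <- rank(c(a, b))
  na <- length(a)
  w_obs <- sum(r[seq_len(na)])
  sets <- utils::combn(length(r), na)
  w_all <- apply(sets, 2, function(i) sum(r[i]))
  if (alternative == "greater") mean(w_all >= w_obs - 1e-9)
  else mean(w_all <= w_obs + 1e-9)
}

# one-sided paired signed-rank p by enumerating all 2^n sign assignments
oracle_signed_rank_p <- function(x, y, alternative = "greater") {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  if (alternative == "greater") mean(v_all >= v_obs - 1e-9)
  else mean(v_all <= v_obs + 1e-9)
}

# AUC by direct pair counting
oracle_auc <- function(probs, labels) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Youden threshold by exhaustive scan over every observed cut point
oracle_youden <- function(probs, y) {
  best <- -Inf; best_t <- NA
  for (t in sort(unique(probs))) {
    sens <- mean(probs[y == 1] >= t)
    spec <- mean(probs[y == 0] < t)
    if (sens + spec > best + 1e-12) { best <- sens + spec; best_t <- t }
  }
  list(threshold = best_t, youden = best)
}

# paired-bootstrap p-value for the difference of two correlated AUCs
oracle_delong_bootstrap <- function(pa, pb, y, n_boot = 2000, seed = 1) {
  withr::with_seed(seed, {
    d_obs <- oracle_auc(pa, y) - oracle_auc(pb, y)
    n <- length(y)
    d <- replicate(n_boot, {
      i <- sample.int(n, replace = TRUE)
      while (length(unique(y[i])) < 2) i <- sample.int(n, replace = TRUE)
      oracle_auc(pa[i], y[i]) - oracle_auc(pb[i], y[i])
    })
    se <- sd(d)
    if (se == 0) return(1)
    2 * pnorm(-abs(d_obs / se))
  })
}
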
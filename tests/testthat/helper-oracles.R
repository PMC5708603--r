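# Independent oracles, deliberately written with different machinery
# than the implementation they check.

# Dense matrix-inverse solution of the restart-diffusion fixed point.
oracle_diffuse_dense <- function(network, seeds, alpha) {
  W <- as.matrix(network$adjacency)
  d <- rowSums(W)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  S <- diag(inv_sqrt) %*% W %*% diag(inv_sqrt)
  y <- as.numeric(network$nodes %in% seeds)
  as.numeric(alpha * solve(diag(nrow(W)) - (1 - alpha) * S, y))
}

# Truncated Neumann series alpha * sum_k (1-alpha)^k S^k y.
oracle_diffuse_series <- function(network, seeds, alpha, K = 400) {
  W <- as.matrix(network$adjacency)
  d <- rowSums(W)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  S <- diag(inv_sqrt) %*% W %*% diag(inv_sqrt)
  y <- as.numeric(network$nodes %in% seeds)
  term <- y
  acc <- y
  for (k in seq_len(K)) {
    term <- (1 - alpha) * (S %*% term)
    acc <- acc + term
  }
  as.numeric(alpha * acc)
}

# Two-sided Fisher exact p by direct hypergeometric enumeration over
# all tables with the observed margins.
oracle_fisher_2x2 <- function(n00, n01, n10, n11) {
  r1 <- n00 + n01; c1 <- n00 + n10; n <- n00 + n01 + n10 + n11
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a) {
    exp(lchoose(c1, a) + lchoose(n - c1, r1 - a) - lchoose(n, r1))
  }, 0)
  obs <- probs[n00 - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exact one-sided ("greater") rank-sum p-value by exhaustive
# enumeration of all assignments of the pooled values to the two
# groups; handles ties by construction.
oracle_wilcoxon_greater <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(n, nx)
  stats <- colSums(matrix(r[combs], nrow = nx))
  mean(stats >= obs - 1e-9)
}

# AUC by brute-force enumeration of all (positive, negative) pairs.
oracle_auc_pairs <- function(scores, pos) {
  ps <- scores[pos]; ns <- scores[!pos]
  tot <- 0
  for (p in ps) for (q in ns) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(ps) * length(ns))
}

# Spearman rho from first principles: Pearson correlation of average
# ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Minimal number of seed-size bins: exhaustive search over contiguous
# partitions of the sorted sizes, each part needing an integer center
# within tol of every member.
oracle_min_bins <- function(sizes, tol = 10) {
  sizes <- sort(sizes)
  n <- length(sizes)
  feasible <- function(i, j) {
    seg <- sizes[i:j]
    any(vapply(min(seg):max(seg),
               function(c) all(abs(seg - c) <= tol), TRUE))
  }
  best <- rep(Inf, n + 1)
  best[1] <- 0
  for (j in seq_len(n)) {
    for (i in seq_len(j)) {
      if (feasible(i, j)) best[j + 1] <- min(best[j + 1], best[i] + 1)
    }
  }
  best[n + 1]
}
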
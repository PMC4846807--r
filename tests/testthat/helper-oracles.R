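# Independent brute-force oracles used to validate the analytic estimators.
# These deliberately avoid the package's own code paths.

# Mean species richness over all C(n, m) equally likely subsamples of the
# individuals of a community given as an abundance vector.
oracle_rarefy_q0 <- function(x, m) {
  sp <- rep(seq_along(x), x)
  subs <- utils::combn(length(sp), m)
  mean(apply(subs, 2, function(idx) length(unique(sp[idx]))))
}

# Exhaustive-subsample coverage oracle: pick each individual j in turn, draw
# every subsample of size m from the remaining n - 1 individuals, and count
# how often the subsample misses j's species.  The complement is the
# expected coverage of a size-m sample (Good-Turing construction).
oracle_coverage <- function(x, m) {
  sp <- rep(seq_along(x), x)
  n <- length(sp)
  miss <- vapply(seq_len(n), function(j) {
    others <- sp[-j]
    subs <- utils::combn(n - 1, m)
    mean(apply(subs, 2, function(idx) !(sp[j] %in% others[idx])))
  }, numeric(1))
  1 - mean(miss)
}

# Brute-force group-average agglomeration for small distance matrices.
# Returns merge heights in order and the two-group partition.
oracle_upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partition_k2 <- NULL
  avg_dist <- function(a, b) mean(d[a, b])
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dist_ij <- avg_dist(clusters[[i]], clusters[[j]])
        if (dist_ij < best[1]) best <- c(dist_ij, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters <- c(clusters, list(merged))
    if (length(clusters) == 2) {
      partition_k2 <- clusters
    }
  }
  list(heights = heights, partition_k2 = partition_k2)
}

# Hand Bray-Curtis
oracle_bray <- function(a, b) {
  sum(abs(a - b)) / sum(a + b)
}

# Ewens metacommunity expectation for the abundance spectrum of a sample of
# size J with biodiversity number theta (the m -> 1 limit of the local
# neutral spectrum).
oracle_ewens_phi <- function(n, theta, J) {
  theta / n * exp(lgamma(J + 1) + lgamma(J - n + theta) -
                    lgamma(J + 1 - n) - lgamma(J + theta))
}

# Fine-grid trapezoid evaluation of the neutral sampling-formula integral,
# independent of adaptive quadrature.
oracle_neutral_phi_trapz <- function(n, theta, m, J, grid_n = 20000) {
  gam <- m * (J - 1) / (1 - m)
  y <- seq(0, gam * (1 - 1e-10), length.out = grid_n)
  log_pref <- log(theta) + lgamma(J + 1) + lgamma(gam) - lgamma(J + gam) -
    lgamma(n + 1) - lgamma(J - n + 1)
  f <- exp(lgamma(n + y) - lgamma(1 + y) +
             lgamma(J - n + gam - y) - lgamma(gam - y) -
             y * theta / gam + log_pref)
  sum((f[-1] + f[-grid_n]) / 2 * diff(y))
}

# Observed Hill number computed straight from a probability vector.
oracle_hill_from_p <- function(p, q) {
  p <- p[p > 0]
  if (q == 0) return(length(p))
  if (q == 1) return(exp(-sum(p * log(p))))
  1 / sum(p^2)
}
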
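# Independent brute-force oracles used to check the exact statistics and
# graph routines. These deliberately share no code with the package
# implementations: enumeration and naive matrix recursions only.

# Fisher exact by enumeration over all tables with the observed margins.
# Table probability from the product of binomial coefficients.
oracle_fisher <- function(m, alternative = c("two_sided", "one_sided")) {
  alternative <- match.arg(alternative)
  a <- m[1, 1]
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  if (sum(m) == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(support, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1)
  }, 0)
  if (alternative == "one_sided") {
    sum(prob[support >= a])
  } else {
    p_obs <- prob[support == a]
    sum(prob[prob <= p_obs * (1 + 1e-7)])
  }
}

# Hypergeometric upper tail by direct combinatorial count.
oracle_hypergeom_tail <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Exact Mann-Whitney two-sided p by full enumeration of all
# choose(nx+ny, nx) assignments of the pooled mid-ranks.
oracle_mwu_two_sided <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  ranks <- rank(c(x, y))
  rx_obs <- sum(ranks[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  combos <- utils::combn(n, nx)
  sums <- colSums(matrix(ranks[combos], nrow = nx))
  mean(abs(sums - mu) >= abs(rx_obs - mu) - 1e-9)
}

# KS D by evaluating both ECDFs at every pooled sample point.
oracle_ks_D <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, 0))
}

# All-pairs shortest paths by Floyd-Warshall on an adjacency matrix.
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# Woolf OR recomputed longhand for the inversion property checks.
oracle_or <- function(a, b, c, d) (a * d) / (b * c)

# Every 2x2 table with total count <= max_total.
all_small_tables <- function(max_total) {
  out <- list()
  for (total in 1:max_total) {
    parts <- t(utils::combn(total + 3, 3))
    for (i in seq_len(nrow(parts))) {
      cuts <- parts[i, ]
      out[[length(out) + 1]] <- matrix(c(cuts[1] - 1, cuts[2] - cuts[1] - 1,
                                         cuts[3] - cuts[2] - 1,
                                         total + 3 - cuts[3]), 2, 2)
    }
  }
  out
}
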
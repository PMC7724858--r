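#' Exact and asymptotic statistics for variant, network and cohort analyses
#'
#' @description
#' Self-contained statistical routines used across the pipeline:
#' Fisher's exact test on 2x2 tables, the hypergeometric upper tail used
#' for pathway enrichment, the two-sample Kolmogorov-Smirnov test with the
#' asymptotic Kolmogorov p-value, the exact Mann-Whitney U test (full
#' null-distribution enumeration with mid-rank tie handling), and Woolf
#' confidence intervals for odds ratios with the Haldane-Anscombe zero-cell
#' correction.
#'
#' @name stats_core
NULL

#' 2x2 contingency table of exposure by case-control status
#'
#' @param exposed_cases,exposed_controls,unexposed_cases,unexposed_controls
#'   non-negative integer cell counts.
#' @return An object of class `contingency_2x2` (named list of the four
#'   cells, in the order given above).
#' @examples
#' contingency_2x2(201, 127, 432, 438)
#' @export
contingency_2x2 <- function(exposed_cases, exposed_controls,
                            unexposed_cases, unexposed_controls) {
  cells <- c(exposed_cases = exposed_cases,
             exposed_controls = exposed_controls,
             unexposed_cases = unexposed_cases,
             unexposed_controls = unexposed_controls)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    stop("contingency_2x2: all cells must be non-negative integers")
  }
  if (sum(cells) == 0) {
    stop("contingency_2x2: at least one cell must be non-zero")
  }
  structure(stats::setNames(as.list(as.integer(cells)), names(cells)),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(unlist(x), 2, 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("cases", "controls")))
  print(m)
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test conditioning on both margins. The one-sided
#' p-value is the upper tail P(X >= a) for the top-left cell; the
#' two-sided p-value sums the probabilities of all tables (with the same
#' margins) whose probability does not exceed that of the observed table.
#'
#' @param table 2x2 integer matrix, or a `contingency_2x2`.
#' @param alternative `"one_sided"` (upper tail in the top-left cell) or
#'   `"two_sided"`.
#' @return The exact p-value.
#' @examples
#' fisher_exact(matrix(c(6, 0, 4, 10), 2, 2), "one_sided")
#' @export
fisher_exact <- function(table, alternative = c("two_sided", "one_sided")) {
  alternative <- match.arg(alternative)
  m <- as_2x2_matrix(table)
  a <- m[1, 1]
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1])
  if (sum(m) == 0) return(1)
  # X ~ Hypergeometric: c1 draws from r1 "row-1" and r2 "row-2" items
  lo <- max(0L, c1 - r2)
  hi <- min(r1, c1)
  if (alternative == "one_sided") {
    p <- stats::phyper(a - 1, r1, r2, c1, lower.tail = FALSE)
  } else {
    support <- lo:hi
    probs <- stats::dhyper(support, r1, r2, c1)
    # tolerance guards against probabilities equal up to rounding
    p <- sum(probs[probs <= probs[support == a] * (1 + 1e-7)])
  }
  min(1, p)
}

as_2x2_matrix <- function(table) {
  if (inherits(table, "contingency_2x2")) {
    m <- matrix(unlist(table), 2, 2, byrow = TRUE)
  } else {
    m <- as.matrix(table)
  }
  if (!all(dim(m) == c(2, 2))) stop("expected a 2x2 table")
  if (any(m < 0) || any(m != floor(m))) {
    stop("table cells must be non-negative integers")
  }
  m
}

#' Hypergeometric upper tail P(X >= k)
#'
#' Probability that a size-`n` draw (without replacement) from a population
#' of `N` objects of which `K` are marked contains at least `k` marked
#' objects. This is the enrichment p-value used for pathway ranking.
#'
#' @param k observed overlap count.
#' @param K number of marked objects (pathway size).
#' @param n draw size (query size).
#' @param N population size (background size).
#' @return Upper-tail probability, a number in \[0, 1\].
#' @examples
#' hypergeom_tail(5, 5, 5, 10)  # 1/252
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    stop("hypergeom_tail: infeasible arguments (need k <= min(K, n), K, n <= N)")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes D, the supremum distance between the two empirical CDFs, and an
#' asymptotic two-sided p-value from the Kolmogorov distribution evaluated
#' at `sqrt(n_eff) * D` with effective size `n_eff = n_x n_y / (n_x + n_y)`.
#' No exact small-sample p-value is computed; the `exact` flag in the
#' result is therefore always `FALSE`.
#'
#' @param x,y numeric samples (non-empty).
#' @return List with elements `D`, `p`, `n_eff`, `exact`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("ks_two_sample: both samples must be non-empty")
  }
  nx <- length(x); ny <- length(y)
  pooled <- sort(unique(c(x, y)))
  ecdf_x <- stats::ecdf(x)(pooled)
  ecdf_y <- stats::ecdf(y)(pooled)
  D <- max(abs(ecdf_x - ecdf_y))
  n_eff <- nx * ny / (nx + ny)
  p <- kolmogorov_sf(sqrt(n_eff) * D)
  list(D = D, p = p, n_eff = n_eff, exact = FALSE)
}

# Survival function of the Kolmogorov distribution:
# Q(t) = 2 * sum_{j>=1} (-1)^(j-1) exp(-2 j^2 t^2)
kolmogorov_sf <- function(t) {
  if (t <= 0) return(1)
  j <- seq_len(200)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))
  min(1, max(0, p))
}

#' Exact Mann-Whitney U test
#'
#' U is `min(U_x, U_y)`. For small samples (`n_x + n_y <= max_exact`) the
#' p-value is exact: the null distribution of the rank sum over all
#' `choose(n_x + n_y, n_x)` assignments of the pooled mid-ranks is computed
#' by a subset-sum recursion, which is equivalent to full enumeration and
#' handles ties through the shared mid-rank values. Larger samples fall
#' back to the normal approximation with tie correction and are flagged
#' `exact = FALSE`.
#'
#' @param x,y numeric samples (non-empty).
#' @param two_sided logical; if `FALSE`, the one-sided p-value for the
#'   alternative "x tends smaller" (small rank sum of `x`) is returned.
#' @param max_exact largest pooled size for which enumeration is used.
#' @return List with elements `U`, `p`, `exact`.
#' @export
mann_whitney_exact <- function(x, y, two_sided = TRUE, max_exact = 25) {
  if (length(x) == 0 || length(y) == 0) {
    stop("mann_whitney_exact: both samples must be non-empty")
  }
  nx <- length(x); ny <- length(y)
  n <- nx + ny
  ranks <- rank(c(x, y))           # mid-ranks for ties
  rx <- sum(ranks[seq_len(nx)])
  ux <- rx - nx * (nx + 1) / 2
  uy <- nx * ny - ux
  U <- min(ux, uy)
  if (n <= max_exact) {
    # exact null distribution of the rank sum of the x-sample
    p <- mwu_exact_p(ranks, nx, rx, two_sided)
    list(U = U, p = p, exact = TRUE)
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(ranks)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma <- sqrt(nx * ny / 12 * ((n + 1) - tie_corr))
    if (sigma == 0) return(list(U = U, p = 1, exact = FALSE))
    z <- (U - mu) / sigma
    p_one <- stats::pnorm(z)
    p <- if (two_sided) min(1, 2 * p_one) else p_one
    list(U = U, p = p, exact = FALSE)
  }
}

# Exact p for the rank-sum statistic by subset-sum DP over the pooled
# mid-ranks (doubled so all values are integers). Equivalent to
# enumerating all choose(n, nx) assignments.
mwu_exact_p <- function(ranks, nx, rx_obs, two_sided) {
  r2 <- as.integer(round(2 * ranks))
  n <- length(r2)
  total_max <- sum(sort(r2, decreasing = TRUE)[seq_len(nx)])
  # counts[m + 1, s + 1] = number of m-subsets with doubled-rank sum s
  counts <- matrix(0, nrow = nx + 1, ncol = total_max + 1)
  counts[1, 1] <- 1
  for (v in r2) {
    upper <- min(nx, n)
    for (m in seq(from = upper, to = 1)) {
      shifted <- c(rep(0, v), counts[m, seq_len(total_max + 1 - v)])
      counts[m + 1, ] <- counts[m + 1, ] + shifted
    }
  }
  dist <- counts[nx + 1, ]
  total <- sum(dist)
  sums <- (seq_along(dist) - 1) / 2           # back to mid-rank scale
  obs <- rx_obs
  mu <- nx * (n + 1) / 2                      # null mean of the rank sum
  eps <- 1e-9
  if (two_sided) {
    dev <- abs(obs - mu)
    p <- sum(dist[abs(sums - mu) >= dev - eps]) / total
  } else {
    p <- sum(dist[sums <= obs + eps]) / total
  }
  min(1, p)
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' Crude odds ratio `ad / bc` for a 2x2 exposure-by-status table with the
#' Woolf (log-normal) interval `exp(log OR +- 1.96 sqrt(1/a+1/b+1/c+1/d))`.
#' If any cell is zero, 0.5 is added to every cell first
#' (Haldane-Anscombe) and the result is flagged `corrected`. The constant
#' 1.96 is fixed rather than looked up so reported intervals match the
#' conventional printed form exactly.
#'
#' @param table a `contingency_2x2` or 2x2 matrix
#'   (rows exposed/unexposed, columns cases/controls).
#' @return List of class `or_result`: `odds_ratio`, `ci_low`, `ci_high`,
#'   `corrected`.
#' @examples
#' woolf_or(contingency_2x2(201, 127, 432, 438))  # OR 1.60 (1.24, 2.08)
#' @export
woolf_or <- function(table) {
  m <- as_2x2_matrix(table)
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  structure(list(odds_ratio = or,
                 ci_low = exp(log(or) - 1.96 * se),
                 ci_high = exp(log(or) + 1.96 * se),
                 corrected = corrected),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f, %.2f)%s\n",
              x$odds_ratio, x$ci_low, x$ci_high,
              if (x$corrected) " [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}
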
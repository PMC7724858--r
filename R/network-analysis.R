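#' Interaction-network construction and main-graph statistics
#'
#' @description
#' An individual's variant-containing genes are projected onto a
#' STRING-style interaction-edge table. An edge is kept when both
#' endpoints carry variants and its combined evidence score — a noisy-OR
#' aggregation `1 - prod(1 - s_c)` over the selected evidence channels
#' (experiments, databases, gene fusion by default) — reaches the
#' high-confidence threshold 0.700 (inclusive). The topology of the
#' "main graph" (largest connected component) is then summarised:
#' characteristic path length, shortest-path and degree histograms,
#' average neighbor count, and a log-log least-squares power-law fit of
#' the degree distribution.
#'
#' The combined score deliberately omits STRING's internal prior
#' correction, which is version-dependent; this is a documented
#' reconstruction of "combined score" behaviour.
#'
#' @name network_analysis
NULL

PPI_CHANNELS <- c("experiments", "databases", "fusion")

#' Build the thresholded interaction graph over a gene set
#'
#' @param edges edge data.frame with columns `protein1`, `protein2` and
#'   per-channel integer scores on the 0-1000 scale (divided by 1000 on
#'   read).
#' @param genes character vector: the individual's variant-containing
#'   genes. All become nodes, including isolates.
#' @param score_threshold minimum combined score (default 0.700,
#'   inclusive).
#' @param channels evidence channels entering the combined score.
#' @return An [igraph::graph] with `name` vertex attribute; simple
#'   (no loops or multi-edges).
#' @export
build_graph <- function(edges, genes, score_threshold = 0.700,
                        channels = PPI_CHANNELS) {
  genes <- sort(unique(as.character(genes)))
  unknown <- setdiff(channels, names(edges))
  if (length(unknown)) {
    stop("build_graph: unknown channel(s): ", paste(unknown, collapse = ", "))
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(genes), name = genes)
  if (length(genes) == 0 || nrow(edges) == 0) return(g)
  in_set <- edges$protein1 %in% genes & edges$protein2 %in% genes &
    edges$protein1 != edges$protein2
  sub <- edges[in_set, , drop = FALSE]
  if (nrow(sub) == 0) return(g)
  score_mat <- as.matrix(sub[, channels, drop = FALSE]) / 1000
  combined <- 1 - apply(1 - score_mat, 1, prod)
  keep <- combined >= score_threshold - 1e-9
  sub <- sub[keep, , drop = FALSE]
  if (nrow(sub) == 0) return(g)
  # canonical order + dedup so reciprocal duplicates collapse
  a <- pmin(sub$protein1, sub$protein2)
  b <- pmax(sub$protein1, sub$protein2)
  pair <- paste(a, b)
  first <- !duplicated(pair)
  el <- rbind(a[first], b[first])
  igraph::add_edges(g, as.vector(el))
}

#' Extract the main graph (largest connected component)
#'
#' Ties on component size are broken deterministically by taking the
#' component containing the lexicographically smallest node name.
#'
#' @param graph an igraph object with named vertices.
#' @return The induced subgraph on the largest component (empty graph in,
#'   empty graph out).
#' @export
main_graph <- function(graph) {
  if (igraph::vcount(graph) == 0) return(graph)
  comp <- igraph::components(graph)
  max_size <- max(comp$csize)
  cand <- which(comp$csize == max_size)
  if (length(cand) > 1) {
    first_member <- vapply(cand, function(ci) {
      min(igraph::V(graph)$name[comp$membership == ci])
    }, "")
    cand <- cand[order(first_member)[1]]
  }
  igraph::induced_subgraph(graph, which(comp$membership == cand))
}

#' Topology statistics of a graph's main component
#'
#' All statistics are computed on the main graph of `graph`:
#' characteristic path length (mean shortest-path distance over unordered
#' node pairs, all connected within the main graph), shortest-path and
#' degree histograms, and average neighbor count `2E/N`. A single-node
#' (or empty) main graph has no pairs; its path length is reported as 0
#' with `degenerate = TRUE`.
#'
#' @param graph an igraph object (the full per-individual graph).
#' @return List of class `main_graph_stats`: `n_total`, `n_main`,
#'   `fraction`, `char_path_length`, `avg_neighbors`,
#'   `shortest_path_histogram` (named count vector over distances),
#'   `degree_histogram` (named count vector over degrees),
#'   `powerlaw_slope`, `powerlaw_r2` (NA when the degree support is too
#'   small), `degenerate`.
#' @export
graph_stats <- function(graph) {
  n_total <- igraph::vcount(graph)
  mg <- main_graph(graph)
  n_main <- igraph::vcount(mg)
  degenerate <- n_main < 2
  if (n_main == 0) {
    sp_hist <- integer(0); deg_hist <- integer(0)
    cpl <- 0; avg_nb <- 0
  } else {
    d <- igraph::distances(mg)
    ut <- d[upper.tri(d)]
    cpl <- if (degenerate) 0 else mean(ut)
    sp_hist <- if (degenerate) integer(0) else table(ut)
    deg <- igraph::degree(mg)
    avg_nb <- mean(deg)
    deg_hist <- table(deg)
  }
  pl <- tryCatch(powerlaw_fit(deg_hist),
                 error = function(e) list(slope = NA_real_, r2 = NA_real_))
  structure(list(
    n_total = n_total, n_main = n_main,
    fraction = if (n_total > 0) n_main / n_total else 0,
    char_path_length = cpl, avg_neighbors = avg_nb,
    shortest_path_histogram = sp_hist, degree_histogram = deg_hist,
    powerlaw_slope = pl$slope, powerlaw_r2 = pl$r2,
    degenerate = degenerate), class = "main_graph_stats")
}

#' @export
print.main_graph_stats <- function(x, ...) {
  cat(sprintf("main graph: %d / %d nodes (fraction %.3f)\n",
              x$n_main, x$n_total, x$fraction))
  cat(sprintf("characteristic path length %.3f, avg neighbors %.3f\n",
              x$char_path_length, x$avg_neighbors))
  if (!is.na(x$powerlaw_slope)) {
    cat(sprintf("power-law fit: slope %.3f (r2 %.3f)\n",
                x$powerlaw_slope, x$powerlaw_r2))
  }
  invisible(x)
}

#' Power-law fit of a degree histogram
#'
#' Least-squares line on `(log10 k, log10 n(k))` over degrees `k > 0`
#' with non-zero counts, matching the straight-line fits conventionally
#' drawn on log-log degree distributions. The slope estimates the
#' power-law exponent (negative for decaying distributions).
#'
#' @param degree_histogram named count vector (names are degrees), as in
#'   [graph_stats()], or a table.
#' @return List with `slope` and `r2`.
#' @export
powerlaw_fit <- function(degree_histogram) {
  k <- as.numeric(names(degree_histogram))
  n_k <- as.numeric(degree_histogram)
  keep <- k > 0 & n_k > 0
  k <- k[keep]; n_k <- n_k[keep]
  if (length(k) < 3) {
    stop("powerlaw_fit: need >= 3 distinct non-zero degrees with counts")
  }
  fit <- stats::lm(log10(n_k) ~ log10(k))
  # r-squared computed directly: summary.lm warns on perfect fits
  res <- stats::residuals(fit)
  ss_tot <- sum((log10(n_k) - mean(log10(n_k)))^2)
  r2 <- if (ss_tot < 1e-12) 1 else 1 - sum(res^2) / ss_tot
  list(slope = unname(stats::coef(fit)[2]), r2 = r2)
}

#' Main-graph size and fraction for one individual
#'
#' Composes [build_graph()] and [main_graph()]: the coordinate pair
#' (number of main-graph nodes, fraction of all variant genes in the
#' main graph) used to compare individuals.
#'
#' @inheritParams build_graph
#' @return List with `n_main` and `fraction`.
#' @export
main_fraction_point <- function(genes, edges, score_threshold = 0.700,
                                channels = PPI_CHANNELS) {
  g <- build_graph(edges, genes, score_threshold, channels)
  mg <- main_graph(g)
  n_total <- igraph::vcount(g)
  list(n_main = igraph::vcount(mg),
       fraction = if (n_total > 0) igraph::vcount(mg) / n_total else 0)
}

#' Compare a graph metric between two groups of individuals
#'
#' @param stats_a,stats_b lists of `main_graph_stats` (one per
#'   individual).
#' @param metric `"neighbors"` (per-node degree lists pooled within each
#'   group), `"n_main"` or `"fraction"` (per-individual scalars).
#' @param test `"ks"` (two-tailed Kolmogorov-Smirnov) or `"mwu"`
#'   (two-tailed Mann-Whitney U).
#' @return The test p-value.
#' @export
compare_groups <- function(stats_a, stats_b,
                           metric = c("neighbors", "n_main", "fraction"),
                           test = c("ks", "mwu")) {
  metric <- match.arg(metric)
  test <- match.arg(test)
  pull <- function(stats) {
    if (metric == "neighbors") {
      unlist(lapply(stats, function(s) {
        rep(as.numeric(names(s$degree_histogram)),
            as.numeric(s$degree_histogram))
      }))
    } else {
      vapply(stats, `[[`, 0, metric)
    }
  }
  x <- pull(stats_a); y <- pull(stats_b)
  if (test == "ks") ks_two_sample(x, y)$p
  else mann_whitney_exact(x, y, two_sided = TRUE)$p
}
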
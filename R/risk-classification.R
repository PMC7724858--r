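#' Two-pathway risk features, clustering, SVM boundary and decision rule
#'
#' @description
#' Each individual is summarised by three features: the number of
#' variant-containing genes in a PI3K/AKT-type pathway, the number in a
#' pathways-in-cancer-type pathway, and the fraction of variant genes in
#' the interaction main graph. Individuals are clustered into two groups
#' by average-linkage hierarchical clustering on the two counts; a
#' maximum-margin linear boundary ("optimal division line") is fitted to
#' labelled groups; and an explicit threshold rule (> 15 PI3K/AKT genes
#' and > 10 cancer-pathway genes, with main-graph fraction > 0.60 as a
#' parallel supporting criterion) assigns high/low risk.
#'
#' The SVM is a from-scratch exact 2-D solver: for separable data the
#' maximum-margin separator is the perpendicular bisector of the
#' shortest segment joining the two classes' convex hulls; for
#' non-separable data a deterministic full-batch subgradient descent on
#' the soft-margin objective (penalty 1.0) is used and flagged.
#'
#' @name risk_classification
NULL

#' Assemble risk features for one individual
#'
#' @param genes the individual's nonsynonymous variant-containing genes.
#' @param db a `pathway_db` containing both pathway ids.
#' @param edges interaction-edge table (see [build_graph()]).
#' @param pi3k_id,cancer_id pathway ids of the two feature pathways.
#' @param id individual identifier carried through to reports.
#' @param label optional group label.
#' @param score_threshold,channels passed to [build_graph()].
#' @return List of class `risk_features`: `individual_id`,
#'   `n_pi3k_genes`, `n_cancer_pathway_genes`, `main_fraction`, `label`.
#' @export
extract_features <- function(genes, db, edges, pi3k_id, cancer_id,
                             id = "individual", label = "unknown",
                             score_threshold = 0.700,
                             channels = PPI_CHANNELS) {
  missing_ids <- setdiff(c(pi3k_id, cancer_id), names(db$sets))
  if (length(missing_ids)) {
    stop("extract_features: pathway id(s) not in db: ",
         paste(missing_ids, collapse = ", "))
  }
  counts <- pathway_counts(genes, db)
  mf <- main_fraction_point(genes, edges, score_threshold, channels)
  structure(list(individual_id = id,
                 n_pi3k_genes = unname(counts[pi3k_id]),
                 n_cancer_pathway_genes = unname(counts[cancer_id]),
                 main_fraction = mf$fraction,
                 n_main = mf$n_main,
                 label = label),
            class = "risk_features")
}

features_matrix <- function(features) {
  stopifnot(is.list(features), length(features) > 0)
  m <- cbind(n_pi3k = vapply(features, `[[`, 0, "n_pi3k_genes"),
             n_cancer = vapply(features, `[[`, 0, "n_cancer_pathway_genes"))
  rownames(m) <- vapply(features, `[[`, "", "individual_id")
  m
}

#' Unsupervised two-group clustering on the two pathway counts
#'
#' Agglomerative hierarchical clustering (Euclidean distance, average
#' linkage) on (n_pi3k, n_cancer), cut at two clusters. The cluster
#' containing the individual with the largest feature sum is reported
#' first so group identity does not depend on input order.
#'
#' @param features list of `risk_features` (>= 2).
#' @return List of two character vectors of individual ids.
#' @export
cluster_two_groups <- function(features) {
  if (length(features) < 2) {
    stop("cluster_two_groups: need at least 2 individuals")
  }
  m <- features_matrix(features)
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "average")
  cl <- stats::cutree(hc, k = 2)
  top <- names(which.max(rowSums(m)))
  first <- cl[top]
  list(sort(names(cl)[cl == first]), sort(names(cl)[cl != first]))
}

#' Maximum-margin linear decision boundary ("optimal division line")
#'
#' @param features list of `risk_features`, or a 2-column numeric matrix.
#' @param labels vector with exactly two distinct values; the second
#'   sorted level is the positive class (predicted `+1` side).
#' @param C soft-margin penalty used only when the classes are not
#'   linearly separable (default 1.0).
#' @return List of class `linear_boundary`: `weights` (2-vector),
#'   `intercept` (decision value is `weights . x + intercept`),
#'   `margin` (geometric margin; for the soft-margin fall-back, half the
#'   slab width of the fitted boundary), `separable`, `levels`.
#' @export
fit_boundary <- function(features, labels, C = 1.0) {
  x <- if (is.matrix(features)) features else features_matrix(features)
  stopifnot(ncol(x) == 2, nrow(x) == length(labels))
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2) {
    stop("fit_boundary: need exactly two classes, got ", length(lev))
  }
  y <- ifelse(as.character(labels) == lev[2], 1, -1)
  hull_fit <- hard_margin_2d(x, y)
  if (!is.null(hull_fit)) {
    out <- c(hull_fit, list(separable = TRUE, levels = lev))
  } else {
    soft <- soft_margin_gd(x, y, C)
    out <- c(soft, list(separable = FALSE, levels = lev))
  }
  structure(out, class = "linear_boundary")
}

#' Predict class labels from a fitted linear boundary
#' @param object a `linear_boundary`.
#' @param newdata 2-column matrix (or list of `risk_features`).
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.linear_boundary <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else features_matrix(newdata)
  s <- drop(x %*% object$weights) + object$intercept
  ifelse(s >= 0, object$levels[2], object$levels[1])
}

# Exact hard-margin separator in 2D via closest points between convex
# hulls: the max-margin hyperplane is the perpendicular bisector of the
# shortest segment joining conv(A) and conv(B). Returns NULL when the
# hulls intersect (non-separable).
hard_margin_2d <- function(x, y) {
  A <- x[y == -1, , drop = FALSE]
  B <- x[y == 1, , drop = FALSE]
  cp <- closest_hull_points(A, B)
  if (is.null(cp)) return(NULL)
  w <- cp$pb - cp$pa
  gap <- sqrt(sum(w^2))
  if (gap < 1e-9) return(NULL)              # touching hulls
  mid <- (cp$pa + cp$pb) / 2
  # scale so |w . x + b| = 1 at the closest points
  w <- 2 * w / gap^2
  b <- -sum(w * mid)
  # feasibility check: every point on its own side with margin >= 1
  s <- drop(x %*% w) + b
  if (any(y * s < 1 - 1e-6)) return(NULL)
  list(weights = w, intercept = b, margin = gap / 2)
}

# Closest pair of points between two convex hulls (vertex-vertex and
# vertex-edge candidates; sufficient in 2D). NULL if hulls overlap.
closest_hull_points <- function(A, B) {
  ha <- hull_vertices(A); hb <- hull_vertices(B)
  if (hulls_intersect(ha, hb)) return(NULL)
  best <- NULL; best_d <- Inf
  consider <- function(pa, pb) {
    d <- sum((pa - pb)^2)
    if (d < best_d) { best_d <<- d; best <<- list(pa = pa, pb = pb) }
  }
  for (i in seq_len(nrow(ha))) {
    for (j in seq_len(nrow(hb))) consider(ha[i, ], hb[j, ])
  }
  # vertices of one hull against the other hull's edges (closed polygon)
  project_onto_edges <- function(p, Q) {
    nq <- nrow(Q)
    if (nq < 2) return(NULL)
    out <- list()
    for (j in seq_len(nq)) {
      q1 <- Q[j, ]; q2 <- Q[if (j == nq) 1 else j + 1, ]
      seg <- q2 - q1
      len2 <- sum(seg^2)
      if (len2 == 0) next
      t <- max(0, min(1, sum((p - q1) * seg) / len2))
      out[[length(out) + 1]] <- q1 + t * seg
    }
    out
  }
  for (i in seq_len(nrow(ha))) {
    for (proj in project_onto_edges(ha[i, ], hb)) consider(ha[i, ], proj)
  }
  for (j in seq_len(nrow(hb))) {
    for (proj in project_onto_edges(hb[j, ], ha)) consider(proj, hb[j, ])
  }
  best
}

hull_vertices <- function(P) {
  P <- unique(P)
  if (nrow(P) <= 2) return(P)
  idx <- grDevices::chull(P)
  P[idx, , drop = FALSE]
}

# Separating-axis test on hull vertex sets: convex sets are disjoint iff
# some direction strictly separates them. Candidate axes: normals of all
# hull edges of both polygons (and the degenerate point/segment cases).
hulls_intersect <- function(ha, hb) {
  axes <- list()
  add_edge_normals <- function(P) {
    n <- nrow(P)
    if (n < 2) return()
    for (j in seq_len(n)) {
      e <- P[if (j == n) 1 else j + 1, ] - P[j, ]
      if (sum(e^2) > 0) axes[[length(axes) + 1]] <<- c(-e[2], e[1])
    }
  }
  add_edge_normals(ha); add_edge_normals(hb)
  # point-point / point-segment degenerate cases: use connecting directions
  for (i in seq_len(nrow(ha))) {
    for (j in seq_len(nrow(hb))) {
      d <- hb[j, ] - ha[i, ]
      if (sum(d^2) > 0) axes[[length(axes) + 1]] <- d
    }
  }
  if (length(axes) == 0) return(TRUE)        # identical single points
  for (ax in axes) {
    pa <- drop(ha %*% ax); pb <- drop(hb %*% ax)
    if (max(pa) < min(pb) - 1e-12 || max(pb) < min(pa) - 1e-12) return(FALSE)
  }
  TRUE
}

# Deterministic full-batch subgradient descent on
# 0.5 ||w||^2 + C sum hinge(1 - y (w.x + b)).
soft_margin_gd <- function(x, y, C, iters = 5000) {
  w <- c(0, 0); b <- 0
  n <- nrow(x)
  for (t in seq_len(iters)) {
    s <- drop(x %*% w) + b
    active <- y * s < 1
    grad_w <- w - C * colSums(x[active, , drop = FALSE] * y[active])
    grad_b <- -C * sum(y[active])
    eta <- 1 / (1 + t / 50)
    w <- w - eta * grad_w / n
    b <- b - eta * grad_b / n
    if (sqrt(sum(grad_w^2)) + abs(grad_b) < 1e-10) break
  }
  nw <- sqrt(sum(w^2))
  list(weights = w, intercept = b,
       margin = if (nw > 0) 1 / nw else 0)
}

#' Explicit threshold decision rule
#'
#' High risk requires strictly more than `pi3k_min` variant genes in the
#' PI3K/AKT-type pathway AND strictly more than `cancer_min` in the
#' cancer-pathway set. The main-graph fraction exceeding `fraction_min`
#' is reported as a separate supporting flag, not a conjunct, because it
#' is an independent parallel criterion.
#'
#' @param features a `risk_features` (or any list with the three fields).
#' @param pi3k_min,cancer_min,fraction_min thresholds (defaults 15, 10,
#'   0.60).
#' @return List: `call` (`"high_risk"`/`"low_risk"`),
#'   `main_graph_support` (logical).
#' @export
decision_rule <- function(features, pi3k_min = 15, cancer_min = 10,
                          fraction_min = 0.60) {
  f <- as.list(features)
  call <- if (f$n_pi3k_genes > pi3k_min &&
              f$n_cancer_pathway_genes > cancer_min) "high_risk" else "low_risk"
  list(call = call, main_graph_support = f$main_fraction > fraction_min)
}
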
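#' Pathway gene-set loading, counting, and enrichment ranking
#'
#' @description
#' Gene sets are exchanged in GMT format. For an individual's
#' variant-containing genes we compute per-pathway overlap counts and a
#' hypergeometric upper-tail enrichment p-value against a background of
#' all genes in the database union (configurable). Pathways are ranked
#' by ascending p-value with deterministic tie-breaking; top-k lists can
#' be intersected across individuals. Ranking by raw overlap count is
#' available as an alternative because the ranking criterion of the
#' online enrichment tools this replaces is not published.
#'
#' @name pathway_analysis
NULL

#' Load a pathway database from GMT text
#'
#' @param text GMT content: character vector of lines, one string with
#'   newlines, or a file path. Each line is `id<TAB>description<TAB>gene...`.
#' @param background optional character vector overriding the background
#'   gene universe (default: union of all pathway genes).
#' @return List of class `pathway_db`: `sets` (named list of gene
#'   vectors, each with a `description` attribute), `background`,
#'   `background_size`.
#' @export
load_gmt <- function(text, background = NULL) {
  lines <- as_text_lines(text)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("load_gmt: line %d has fewer than 3 columns", i))
    }
    genes <- unique(fields[-(1:2)])
    attr(genes, "description") <- fields[2]
    sets[[fields[1]]] <- genes
  }
  if (is.null(background)) {
    background <- sort(unique(unlist(sets, use.names = FALSE)))
  }
  structure(list(sets = sets, background = background,
                 background_size = length(background)),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("pathway_db: %d sets, background %d genes\n",
              length(x$sets), x$background_size))
  invisible(x)
}

#' Per-pathway overlap counts for a gene set
#'
#' @param genes character vector of query genes.
#' @param db a `pathway_db`.
#' @return named integer vector: pathway id -> |query intersect pathway|.
#' @export
pathway_counts <- function(genes, db) {
  genes <- unique(genes)
  vapply(db$sets, function(s) length(intersect(genes, s)), 1L)
}

#' Rank pathways by hypergeometric enrichment
#'
#' For each pathway, the p-value is `hypergeom_tail(k, K, n, N)` with
#' `N` the background size, `K` the pathway size, `n` the size of the
#' query restricted to the background, and `k` the overlap. Query genes
#' absent from the background are dropped (with a message). Sorting is
#' by ascending p, ties by descending overlap, then pathway id; with
#' `by = "count"` the sort key is descending overlap, then id.
#'
#' @param genes query gene set.
#' @param db a `pathway_db`.
#' @param k number of top pathways to return (default 10).
#' @param by `"p"` (hypergeometric, default) or `"count"`.
#' @return data.frame: `pathway_id`, `overlap_count`, `pathway_size`,
#'   `p_value`, `rank` (1..k).
#' @export
rank_pathways <- function(genes, db, k = 10, by = c("p", "count")) {
  by <- match.arg(by)
  stopifnot(k >= 1)
  genes <- unique(genes)
  in_bg <- genes %in% db$background
  if (any(!in_bg)) {
    message(sprintf("rank_pathways: dropping %d query gene(s) not in background",
                    sum(!in_bg)))
  }
  query <- genes[in_bg]
  if (length(query) > db$background_size) {
    stop("rank_pathways: query larger than background")
  }
  ids <- names(db$sets)
  overlap <- vapply(db$sets, function(s) length(intersect(query, s)), 1L)
  size <- vapply(db$sets, length, 1L)
  p <- vapply(seq_along(ids), function(i) {
    hypergeom_tail(overlap[i], size[i], length(query), db$background_size)
  }, 0)
  ord <- if (by == "p") order(p, -overlap, ids) else order(-overlap, ids)
  top <- head(ord, k)
  data.frame(pathway_id = ids[top], overlap_count = overlap[top],
             pathway_size = size[top], p_value = p[top],
             rank = seq_along(top), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pathways shared by every individual's top-k ranking
#'
#' @param rankings list of ranking data.frames from [rank_pathways()]
#'   (or character vectors of pathway ids).
#' @param k consider only ranks 1..k of each ranking.
#' @return character vector of pathway ids present in all top-k sets.
#' @export
shared_top <- function(rankings, k = 10) {
  if (!is.list(rankings) || length(rankings) == 0) {
    stop("shared_top: need a non-empty list of rankings")
  }
  tops <- lapply(rankings, function(r) {
    if (is.data.frame(r)) head(r$pathway_id[order(r$rank)], k)
    else head(as.character(r), k)
  })
  sort(Reduce(intersect, tops))
}
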
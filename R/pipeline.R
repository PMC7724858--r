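#' End-to-end pipeline orchestration
#'
#' @description
#' Runs the full analysis from a YAML configuration: per individual,
#' pileups are called (Fisher exact, depth filter), germline and — when
#' a cancer pileup is present — somatic variant sets are derived,
#' variants are annotated against the refFlat models, the
#' nonsynonymous gene set is projected onto the interaction network and
#' the pathway database, and risk features are extracted. At cohort
#' level, groups are compared (KS on pooled neighbor counts, MWU on
#' per-individual scalars), top-k pathway rankings are intersected, the
#' individuals are clustered, a linear boundary is fitted, the explicit
#' decision rule is applied, and — when a cohort CSV is configured —
#' the crude odds-ratio table is produced. Reports are written as
#' JSON-lines plus TSV summaries; logging goes to stderr.
#'
#' @name pipeline
NULL

#' Load and validate a pipeline configuration
#'
#' @param path YAML file (see [simulate_all()] for the schema); relative
#'   paths are resolved against the file's directory.
#' @return config list with absolute paths.
#' @export
load_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  absolutize <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) normalizePath(p) else file.path(base, p)
  }
  for (key in c("genome", "refflat", "edges", "gmt", "cohort")) {
    cfg$paths[[key]] <- absolutize(cfg$paths[[key]])
  }
  for (id in names(cfg$paths$individuals)) {
    for (t in intersect(names(cfg$paths$individuals[[id]]),
                        c("blood", "para", "cancer"))) {
      cfg$paths$individuals[[id]][[t]] <-
        absolutize(cfg$paths$individuals[[id]][[t]])
    }
  }
  defaults <- list(alpha = 0.01, min_depth = 10, score_threshold = 0.700,
                   channels = as.list(PPI_CHANNELS), k_top = 10,
                   pi3k_min = 15, cancer_min = 10, fraction_min = 0.60,
                   pi3k_id = "PI3K_AKT_LIKE", cancer_id = "CANCER_LIKE")
  cfg$params <- utils::modifyList(defaults, cfg$params %||% list())
  stopifnot(cfg$params$alpha > 0, cfg$params$alpha < 1,
            cfg$params$min_depth >= 0,
            cfg$params$score_threshold >= 0, cfg$params$score_threshold <= 1)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(...) {
  message(sprintf("[germnet %s] ", format(Sys.time(), "%H:%M:%S")),
          sprintf(...))
}

load_shared_inputs <- function(config) {
  list(genome = read_genome_fasta(config$paths$genome),
       models = parse_refflat(config$paths$refflat),
       edges = read_string_edges(config$paths$edges),
       db = load_gmt(config$paths$gmt))
}

#' Run the per-individual analysis
#'
#' @param config pipeline config (list or YAML path).
#' @param individual_id id present under `paths$individuals`.
#' @param shared optionally, pre-loaded shared inputs (genome, models,
#'   edges, db) to avoid re-reading them per individual.
#' @return List: `individual_id`, `label`, `germline_keys`,
#'   `somatic_keys`, `nonsyn_genes`, `stats` (`main_graph_stats`),
#'   `ranking` (top-k pathways), `features` (`risk_features`),
#'   `decision`.
#' @export
run_individual <- function(config, individual_id, shared = NULL) {
  if (is.character(config)) config <- load_pipeline_config(config)
  ind <- config$paths$individuals[[individual_id]]
  if (is.null(ind)) stop("run_individual: unknown individual: ", individual_id)
  if (is.null(shared)) shared <- load_shared_inputs(config)
  p <- config$params
  t0 <- Sys.time()

  normal_tissue <- if (!is.null(ind$blood)) "blood" else "para"
  if (is.null(ind[[normal_tissue]])) {
    stop("run_individual: need a blood or para pileup for ", individual_id)
  }
  normal_calls <- call_sample(read_pileup(ind[[normal_tissue]]),
                              alpha = p$alpha, min_depth = p$min_depth)
  germline <- germline_set(normal_calls)

  somatic <- character(0)
  if (!is.null(ind$cancer)) {
    para_pileup <- read_pileup(ind[[normal_tissue]])
    cancer_calls <- call_sample(read_pileup(ind$cancer),
                                alpha = p$alpha, min_depth = p$min_depth)
    somatic <- somatic_set(cancer_calls, normal_calls, para_pileup,
                           min_para_depth = p$min_depth)
  }

  ann <- annotate_variants(germline, shared$models, shared$genome)
  genes <- nonsynonymous_genes(ann)
  g <- build_graph(shared$edges, genes, p$score_threshold,
                   unlist(p$channels))
  stats <- graph_stats(g)
  ranking <- rank_pathways(genes, shared$db, k = p$k_top)
  features <- extract_features(genes, shared$db, shared$edges,
                               p$pi3k_id, p$cancer_id,
                               id = individual_id,
                               label = ind$label %||% "unknown",
                               score_threshold = p$score_threshold,
                               channels = unlist(p$channels))
  decision <- decision_rule(features, p$pi3k_min, p$cancer_min,
                            p$fraction_min)
  log_msg("%s: %d germline, %d somatic, %d nonsyn genes, main %d/%d (%.1fs)",
          individual_id, length(germline), length(somatic), length(genes),
          stats$n_main, stats$n_total,
          as.numeric(difftime(Sys.time(), t0, units = "secs")))
  list(individual_id = individual_id, label = ind$label %||% "unknown",
       germline_keys = germline, somatic_keys = somatic,
       nonsyn_genes = genes, stats = stats, ranking = ranking,
       features = features, decision = decision)
}

#' Run the cohort-level analysis
#'
#' @param config pipeline config (list or YAML path).
#' @param outdir optional directory for reports (`individuals.jsonl`,
#'   `features.tsv`, `or_table.tsv`).
#' @return List: `individuals` (per-individual results; failed ones are
#'   dropped with a logged reason), `feature_table`, `comparisons`
#'   (named p-values, NULL with fewer than 2 per group),
#'   `shared_pathways`, `clusters`, `boundary`, `or_table` (NULL if no
#'   cohort file).
#' @export
run_cohort <- function(config, outdir = NULL) {
  if (is.character(config)) config <- load_pipeline_config(config)
  shared <- load_shared_inputs(config)
  ids <- names(config$paths$individuals)
  if (length(ids) == 0) stop("run_cohort: no individuals configured")
  results <- list()
  for (id in ids) {
    res <- tryCatch(run_individual(config, id, shared = shared),
                    error = function(e) {
                      log_msg("individual %s failed: %s", id,
                              conditionMessage(e))
                      NULL
                    })
    if (!is.null(res)) results[[id]] <- res
  }
  if (length(results) == 0) stop("run_cohort: every individual failed")

  labels <- vapply(results, `[[`, "", "label")
  feature_table <- do.call(rbind, lapply(results, function(r) {
    data.frame(individual_id = r$individual_id, label = r$label,
               n_pi3k_genes = r$features$n_pi3k_genes,
               n_cancer_pathway_genes = r$features$n_cancer_pathway_genes,
               n_main = r$stats$n_main, n_total = r$stats$n_total,
               main_fraction = r$features$main_fraction,
               char_path_length = r$stats$char_path_length,
               avg_neighbors = r$stats$avg_neighbors,
               decision = r$decision$call,
               main_graph_support = r$decision$main_graph_support,
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  grp_a <- results[labels == "familial_patient"]
  grp_b <- results[labels == "control"]
  comparisons <- NULL
  if (length(grp_a) >= 2 && length(grp_b) >= 2) {
    sa <- lapply(grp_a, `[[`, "stats"); sb <- lapply(grp_b, `[[`, "stats")
    comparisons <- c(
      ks_neighbors = compare_groups(sa, sb, "neighbors", "ks"),
      mwu_n_main = compare_groups(sa, sb, "n_main", "mwu"),
      mwu_fraction = compare_groups(sa, sb, "fraction", "mwu"))
  } else {
    log_msg("fewer than 2 individuals per group; comparisons skipped")
  }

  shared_pw <- if (length(grp_a) > 0) {
    shared_top(lapply(grp_a, `[[`, "ranking"), k = config$params$k_top)
  } else character(0)

  clusters <- NULL; boundary <- NULL
  feats <- lapply(results, `[[`, "features")
  if (length(feats) >= 2) clusters <- cluster_two_groups(feats)
  if (length(grp_a) >= 1 && length(grp_b) >= 1) {
    boundary <- fit_boundary(feats, ifelse(labels == "familial_patient",
                                           "familial_patient", "other"))
  }

  or_tab <- NULL
  if (!is.null(config$paths$cohort) && file.exists(config$paths$cohort)) {
    records <- read_cohort_csv(config$paths$cohort)
    contrasts <- config$epi$contrasts %||%
      list(list(field = "exposure", level = "yes", reference = "no"))
    or_tab <- or_table(records, contrasts)
  }

  out <- list(individuals = results, feature_table = feature_table,
              comparisons = comparisons, shared_pathways = shared_pw,
              clusters = clusters, boundary = boundary, or_table = or_tab)
  if (!is.null(outdir)) write_cohort_reports(out, outdir)
  out
}

write_cohort_reports <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  jl <- file.path(outdir, "individuals.jsonl")
  con <- file(jl, "w")
  on.exit(close(con))
  for (r in report$individuals) {
    rec <- list(individual_id = r$individual_id, label = r$label,
                n_germline = length(r$germline_keys),
                n_somatic = length(r$somatic_keys),
                nonsyn_genes = r$nonsyn_genes,
                n_main = r$stats$n_main, n_total = r$stats$n_total,
                fraction = r$stats$fraction,
                char_path_length = r$stats$char_path_length,
                avg_neighbors = r$stats$avg_neighbors,
                top_pathways = r$ranking$pathway_id,
                decision = r$decision$call)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  utils::write.table(report$feature_table,
                     file.path(outdir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$or_table)) {
    utils::write.table(report$or_table, file.path(outdir, "or_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(outdir)
}
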
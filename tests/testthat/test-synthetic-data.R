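test_that("sim_config validates probabilities and counts", {
  expect_error(sim_config(error_rate = 1.5), "probabilities")
  expect_error(sim_config(exposure_probs = c(-0.1, 0.5)), "probabilities")
  expect_error(sim_config(n_germline = 5000, n_somatic = 5000,
                          genome_length = 9000, n_genes = 0), "planted sites")
})

test_that("synth_genome produces valid, deterministic gene models", {
  cfg0 <- sim_config(seed = 1, n_genes = 0, genome_length = 500)
  gen0 <- synth_genome(cfg0)
  expect_equal(nrow(gen0$models), 0)
  expect_equal(nchar(gen0$genome[[1]]), 500)

  cfg <- sim_config(seed = 7, n_genes = 20, genome_length = 60000)
  gen <- synth_genome(cfg)
  expect_equal(nrow(gen$models), 20)
  for (i in seq_len(20)) {
    model <- gen$models[i, , drop = FALSE]
    cpos <- germnet:::cds_positions(model)
    expect_equal(length(cpos) %% 3, 0)
    # forced start codon, in translation order
    first <- substring(gen$genome[[1]], cpos[1:3] + 1, cpos[1:3] + 1)
    if (model$strand == "-") {
      first <- unname(c(A = "T", C = "G", G = "C", T = "A")[first])
    }
    expect_equal(paste(first, collapse = ""), "ATG")
  }
  # non-overlapping transcripts
  o <- order(gen$models$tx_start)
  expect_true(all(gen$models$tx_start[o][-1] >=
                    gen$models$tx_end[o][-20]))
  # byte-identical regeneration
  gen2 <- synth_genome(cfg)
  expect_identical(gen, gen2)
  expect_error(synth_genome(sim_config(n_genes = 10, genome_length = 2000)),
               "300")
})

test_that("synth_pileup implements the stated read model", {
  cfg <- sim_config(seed = 2, genome_length = 1500, n_genes = 0,
                    depth_mean = 30, error_rate = 0,
                    n_germline = 30, n_somatic = 10,
                    het_fraction = 0, cancer_fraction = 1)
  gen <- synth_genome(cfg)
  truth <- synth_truth(cfg, gen$genome)
  expect_length(intersect(truth$germline_sites$pos,
                          truth$somatic_sites$pos), 0)
  for (tissue in c("blood", "para", "cancer")) {
    pu <- synth_pileup(gen$genome, truth, cfg, tissue)
    cm <- as.matrix(pu[, c("A", "C", "G", "T")])
    nonref <- pu$depth - cm[cbind(seq_len(nrow(pu)),
                                  match(pu$ref, c("A", "C", "G", "T")))]
    variant_pos <- c(truth$germline_sites$pos,
                     if (tissue == "cancer") truth$somatic_sites$pos)
    # error_rate 0: non-reference reads only at planted sites
    expect_true(all(nonref[-variant_pos] == 0))
    # hom germline: alt count equals depth in every tissue
    g <- truth$germline_sites
    alt_counts <- cm[cbind(g$pos, match(g$alt, c("A", "C", "G", "T")))]
    expect_equal(alt_counts, pu$depth[g$pos])
    # somatic sites at cancer_fraction 1 are alt-only in cancer tissue
    s <- truth$somatic_sites
    som_alt <- cm[cbind(s$pos, match(s$alt, c("A", "C", "G", "T")))]
    if (tissue == "cancer") {
      expect_equal(som_alt, pu$depth[s$pos])
    } else {
      expect_true(all(som_alt == 0))
    }
  }
  expect_error(synth_pileup(gen$genome, truth, cfg, "plasma"))
  # determinism
  expect_identical(synth_pileup(gen$genome, truth, cfg, "blood"),
                   synth_pileup(gen$genome, truth, cfg, "blood"))
})

test_that("het sites obey the binomial law of large numbers", {
  cfg <- sim_config(seed = 3, genome_length = 1000, n_genes = 0,
                    depth_mean = 50, error_rate = 0,
                    n_germline = 1000, n_somatic = 0, het_fraction = 1)
  gen <- synth_genome(cfg)
  truth <- synth_truth(cfg, gen$genome)
  pu <- synth_pileup(gen$genome, truth, cfg, "blood")
  g <- truth$germline_sites
  cm <- as.matrix(pu[, c("A", "C", "G", "T")])
  alt <- cm[cbind(g$pos, match(g$alt, c("A", "C", "G", "T")))]
  frac <- sum(alt) / sum(pu$depth[g$pos])
  expect_gt(frac, 0.48)
  expect_lt(frac, 0.52)
})

test_that("synth_ppi grows a scale-free graph with a planted module", {
  genes <- sprintf("G%03d", 1:250)
  # attachment 1, no module: a tree
  tree_cfg <- sim_config(seed = 4, ppi_nodes = 50, ppi_attach = 1,
                         planted_module_size = 0)
  tree <- synth_ppi(tree_cfg, genes)
  expect_equal(nrow(tree$edges), 49)
  # determinism
  expect_identical(tree$edges, synth_ppi(tree_cfg, genes)$edges)
  # argument errors
  expect_error(synth_ppi(sim_config(ppi_nodes = 5, ppi_attach = 5), genes),
               "ppi_attach")
  expect_error(synth_ppi(sim_config(ppi_nodes = 10), genes[1:5]),
               "gene names")
  # power-law degree distribution of a pure preferential-attachment graph
  pa_cfg <- sim_config(seed = 5, ppi_nodes = 200, ppi_attach = 2,
                       planted_module_size = 0)
  pa <- synth_ppi(pa_cfg, genes)
  g <- build_graph(pa$edges, pa$nodes)
  fit <- powerlaw_fit(graph_stats(g)$degree_histogram)
  expect_gt(fit$slope, -3.5)
  expect_lt(fit$slope, -1.5)
  # edge scores pass the 0.700 combined threshold and are well-formed
  expect_true(all(pa$edges$experiments >= 700))
  expect_true(all(pa$edges$protein1 != pa$edges$protein2))
  expect_false(any(duplicated(paste(pa$edges$protein1, pa$edges$protein2))))
})

test_that("planted-module gene sets are denser than random ones", {
  genes <- sprintf("G%03d", 1:200)
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = 100 + s, ppi_nodes = 120,
                      planted_module_size = 30)
    ppi <- synth_ppi(cfg, genes)
    withr::with_seed(1000 + s, {
      module_set <- sample(ppi$planted_module_genes, 20)
      random_set <- sample(ppi$nodes, 20)
    })
    mf_mod <- main_fraction_point(module_set, ppi$edges)$fraction
    mf_rnd <- main_fraction_point(random_set, ppi$edges)$fraction
    mf_mod > mf_rnd
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("synth_pathways builds the designed overlap structure", {
  genes <- sprintf("G%03d", 1:500)
  module <- genes[1:30]
  pw <- synth_pathways(genes, module, n_pathways = 10, seed = 6)
  expect_equal(names(pw)[1:2], c("PI3K_AKT_LIKE", "CANCER_LIKE"))
  expect_length(pw, 10)
  expect_true(all(module %in% pw$PI3K_AKT_LIKE))
  expect_gt(length(intersect(pw$CANCER_LIKE, pw$PI3K_AKT_LIKE)), 0)
  sizes <- lengths(pw)
  expect_true(all(sizes >= 20 & sizes <= 80))
  # empty module: pathway 1 is purely random but valid
  pw0 <- synth_pathways(genes, character(0), n_pathways = 2, seed = 6)
  expect_gte(length(pw0$PI3K_AKT_LIKE), 20)
  expect_error(synth_pathways(genes, module, n_pathways = 1), "n_pathways")
  # GMT round-trip
  tf <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(pw, tf)
  db <- load_gmt(tf)
  expect_equal(lapply(db$sets, sort), lapply(pw, function(s) sort(c(s))),
               ignore_attr = TRUE)
})

test_that("synth_cohort hits its designed odds ratio", {
  # degenerate: the single exposed case
  tiny <- synth_cohort(sim_config(seed = 7, cohort_sizes = c(1, 5),
                                  exposure_probs = c(1, 0)))
  expect_equal(tiny$cohort$exposure[tiny$cohort$status == "case"], "yes")
  # null design: estimated OR ~ 1 at large n
  null <- synth_cohort(sim_config(seed = 8, cohort_sizes = c(5000, 5000),
                                  exposure_probs = c(0.3, 0.3)))
  tab <- tabulate_exposure(null$cohort, "exposure", "yes", "no")
  expect_equal(woolf_or(tab)$odds_ratio, 1, tolerance = 0.15)
  expect_equal(null$true_or, 1)
  # designed effect: the truth falls in the estimate's Woolf CI >= 93% of
  # seeds. True coverage is ~94.4%; 500 replicates keep the Monte-Carlo
  # error of this estimate (~1%) well inside the band.
  cover <- vapply(1:500, function(s) {
    cc <- synth_cohort(sim_config(seed = s, cohort_sizes = c(2000, 2000),
                                  exposure_probs = c(0.3, 0.15)))
    res <- woolf_or(tabulate_exposure(cc$cohort, "exposure", "yes", "no"))
    res$ci_low <= cc$true_or && cc$true_or <= res$ci_high
  }, TRUE)
  expect_gte(mean(cover), 0.93)
  expect_equal(synth_cohort(sim_config(seed = 1))$true_or, 2.4286,
               tolerance = 1e-4)
  expect_error(synth_cohort(sim_config(seed = 1, cohort_sizes = c(0, 5))),
               "sizes")
})

test_that("synth_gene_sets separates familial and control individuals", {
  cfg <- sim_config(seed = 9)
  genes <- sprintf("G%03d", 1:150)
  ppi <- synth_ppi(cfg, genes)
  sets <- synth_gene_sets(cfg, ppi$planted_module_genes, genes)
  expect_length(sets, 20)
  labels <- vapply(sets, attr, "", "label")
  expect_equal(sum(labels == "familial_patient"), 10)
  fam_overlap <- vapply(sets[labels == "familial_patient"], function(s) {
    length(intersect(s, ppi$planted_module_genes))
  }, 1L)
  expect_true(all(fam_overlap >= 16))
  expect_identical(sets, synth_gene_sets(cfg, ppi$planted_module_genes,
                                         genes))
})

test_that("plant_gene_variants yields protein-altering hits in the right genes", {
  cfg <- sim_config(seed = 10, genome_length = 9000, n_genes = 25)
  gen <- synth_genome(cfg)
  targets <- gen$models$gene_name[c(2, 9, 17)]
  sites <- plant_gene_variants(gen$genome, gen$models, targets, seed = 77)
  expect_equal(nrow(sites), 3)
  ann <- annotate_variants(
    data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
               alt = sites$alt, stringsAsFactors = FALSE),
    gen$models, gen$genome)
  expect_setequal(nonsynonymous_genes(ann), targets)
  expect_error(plant_gene_variants(gen$genome, gen$models, "NOPE", seed = 1),
               "not in models")
})
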
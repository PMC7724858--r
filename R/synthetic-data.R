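#' Seeded synthetic-data generator for every pipeline input
#'
#' @description
#' Because the patient exomes this pipeline was designed around are not
#' publicly available, the generator produces a complete stand-in world
#' from a single seed: a random genome with non-overlapping gene models
#' (refFlat), per-tissue pileups with planted diploid germline SNPs and
#' subclonal somatic variants under a binomial read-sampling/error
#' model, a scale-free (preferential-attachment) interaction network
#' with a planted densely connected module, pathway gene sets (GMT)
#' overlapping the planted module, per-individual variant-gene sets for
#' familial patients and controls, and case-control cohorts with a
#' designed exposure odds ratio.
#'
#' The single global seed expands into fixed per-stage child seeds so
#' stages can be regenerated independently; identical configurations
#' give byte-identical outputs.
#'
#' All distributions are stand-ins (the source study reports only
#' aggregate coverage); what the generator does and does not emulate is
#' documented in the methods vignette.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' @param seed integer master seed.
#' @param genome_length genome size in bases (must be >= 300 * n_genes).
#' @param n_genes number of non-overlapping gene models.
#' @param depth_mean mean sequencing depth (per-position depths are
#'   Poisson so the >= 10x filter is exercised).
#' @param error_rate per-read per-base sequencing error probability.
#' @param het_fraction probability that a planted germline SNP is
#'   heterozygous (default 0.67, the roughly 2:1 het:hom ratio typical
#'   of germline variant sets).
#' @param n_germline,n_somatic numbers of planted background variant
#'   sites.
#' @param cancer_fraction alt-read fraction of somatic sites in cancer
#'   tissue (tumor-purity surrogate, default 0.3).
#' @param ppi_nodes number of network nodes (genes).
#' @param ppi_attach preferential-attachment edges per new node.
#' @param planted_module_size size of the densely connected planted
#'   module (internal edge probability 0.5).
#' @param n_pathways number of pathway gene sets.
#' @param n_familial,n_control individuals per group.
#' @param familial_module_genes mean number of planted-module genes per
#'   familial individual (sd 2, clamped to at least 16).
#' @param familial_filler_genes random additional genes per familial
#'   individual.
#' @param control_genes random genes per control individual.
#' @param cohort_sizes integer pair (cases, controls) for the
#'   epidemiological cohort.
#' @param exposure_probs probability pair (p_case, p_control); the
#'   designed true odds ratio is
#'   `(p_case/(1-p_case)) / (p_control/(1-p_control))`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       genome_length = 60000L, n_genes = 150L,
                       depth_mean = 30, error_rate = 0.005,
                       het_fraction = 0.67,
                       n_germline = 60L, n_somatic = 20L,
                       cancer_fraction = 0.3,
                       ppi_nodes = 120L, ppi_attach = 2L,
                       planted_module_size = 30L,
                       n_pathways = 8L,
                       n_familial = 10L, n_control = 10L,
                       familial_module_genes = 20,
                       familial_filler_genes = 8L,
                       control_genes = 25L,
                       cohort_sizes = c(2000L, 2000L),
                       exposure_probs = c(0.3, 0.15)) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes), depth_mean = depth_mean,
              error_rate = error_rate, het_fraction = het_fraction,
              n_germline = as.integer(n_germline),
              n_somatic = as.integer(n_somatic),
              cancer_fraction = cancer_fraction,
              ppi_nodes = as.integer(ppi_nodes),
              ppi_attach = as.integer(ppi_attach),
              planted_module_size = as.integer(planted_module_size),
              n_pathways = as.integer(n_pathways),
              n_familial = as.integer(n_familial),
              n_control = as.integer(n_control),
              familial_module_genes = familial_module_genes,
              familial_filler_genes = as.integer(familial_filler_genes),
              control_genes = as.integer(control_genes),
              cohort_sizes = as.integer(cohort_sizes),
              exposure_probs = exposure_probs)
  probs <- c(cfg$error_rate, cfg$het_fraction, cfg$cancer_fraction,
             cfg$exposure_probs)
  if (any(probs < 0 | probs > 1)) stop("sim_config: probabilities must be in [0,1]")
  counts <- c(cfg$genome_length, cfg$n_genes, cfg$n_germline, cfg$n_somatic,
              cfg$ppi_nodes, cfg$planted_module_size, cfg$cohort_sizes)
  if (any(counts < 0)) stop("sim_config: counts must be >= 0")
  if (cfg$n_germline + cfg$n_somatic > cfg$genome_length) {
    stop("sim_config: more planted sites than genome positions")
  }
  structure(cfg, class = "sim_config")
}

# fixed per-stage child seeds derived from the master seed
child_seed <- function(config, stage) {
  offsets <- c(genome = 1L, truth = 2L, pileup_blood = 3L, pileup_para = 4L,
               pileup_cancer = 5L, ppi = 6L, pathways = 7L, cohort = 8L,
               gene_sets = 9L, individuals = 10L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (config$seed %% 100000000L) * 20L + offsets[[stage]]
}

#' Generate a random genome and non-overlapping gene models
#'
#' Genes are laid out in equal slots along the genome; each model has
#' 1-2 exons, a CDS spanning the whole transcript whose length is a
#' multiple of 3, a start codon forced into the genome sequence at the
#' CDS start (reverse-complemented on the minus strand), and a random
#' strand. Coordinates are 0-based half-open (refFlat convention).
#'
#' @param config a [sim_config()].
#' @return List: `genome` (named character vector, one chromosome
#'   `chrS`), `models` (gene-model data.frame as in [parse_refflat()]).
#' @export
synth_genome <- function(config) {
  L <- config$genome_length
  n <- config$n_genes
  if (n > 0 && L < 300L * n) {
    stop("synth_genome: genome_length must be >= 300 * n_genes")
  }
  withr::with_seed(child_seed(config, "genome"), {
    genome <- paste(sample(BASES, L, replace = TRUE), collapse = "")
    if (n == 0) {
      out <- list(genome = c(chrS = genome), models = parse_refflat(character(0)))
    } else {
    slot <- L %/% n
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      slot_start <- (i - 1L) * slot
      n_codons <- sample(30:60, 1)           # CDS 90-180 nt
      cds_len <- 3L * n_codons
      two_exon <- stats::runif(1) < 0.5
      intron_len <- if (two_exon) sample(30:60, 1) else 0L
      tx_len <- cds_len + intron_len
      max_off <- slot - tx_len - 20L
      tx_start <- slot_start + 10L + sample.int(max(1L, max_off), 1)
      tx_end <- tx_start + tx_len
      if (two_exon) {
        e1 <- 3L * sample.int(n_codons - 1L, 1)  # codon-aligned split
        exon_starts <- c(tx_start, tx_start + e1 + intron_len)
        exon_ends <- c(tx_start + e1, tx_end)
      } else {
        exon_starts <- tx_start; exon_ends <- tx_end
      }
      rows[[i]] <- data.frame(
        gene_name = sprintf("G%03d", i),
        transcript_id = sprintf("T%03d", i),
        chrom = "chrS",
        strand = if (stats::runif(1) < 0.5) "+" else "-",
        tx_start = tx_start, tx_end = tx_end,
        cds_start = tx_start, cds_end = tx_end,
        exon_count = length(exon_starts), stringsAsFactors = FALSE)
      rows[[i]]$exon_starts <- list(exon_starts)
      rows[[i]]$exon_ends <- list(exon_ends)
    }
    models <- do.call(rbind, rows)
    models$codable <- TRUE
    # force ATG at the first codon of each CDS, in translation order
    genome_chars <- strsplit(genome, "")[[1]]
    for (i in seq_len(n)) {
      cpos <- cds_positions(models[i, , drop = FALSE])
      start_codon <- if (models$strand[i] == "+") c("A", "T", "G")
        else unname(COMPLEMENT[c("A", "T", "G")])
      genome_chars[cpos[1:3] + 1L] <- start_codon
    }
    genome <- paste(genome_chars, collapse = "")
    out <- list(genome = c(chrS = genome), models = models)
    }
    out
  })
}

#' Plant ground-truth variant sites
#'
#' Draws disjoint germline and somatic site sets uniformly over the
#' genome, with random alternative bases, Bernoulli(`het_fraction`)
#' zygosity for germline sites and `cancer_fraction` for somatic sites.
#'
#' @param config a [sim_config()].
#' @param genome named character vector from [synth_genome()].
#' @return List of class `ground_truth`: data.frames `germline_sites`
#'   (`chrom`, `pos`, `ref`, `alt`, `zygosity`) and `somatic_sites`
#'   (`chrom`, `pos`, `ref`, `alt`, `cancer_fraction`).
#' @export
synth_truth <- function(config, genome) {
  chrom <- names(genome)[1]
  seqchars <- strsplit(genome[[1]], "")[[1]]
  withr::with_seed(child_seed(config, "truth"), {
    total <- config$n_germline + config$n_somatic
    pos <- sort(sample.int(length(seqchars), total))
    pick <- sort(sample.int(total, config$n_germline))
    gpos <- pos[pick]; spos <- pos[setdiff(seq_len(total), pick)]
    alt_of <- function(ref) vapply(ref, function(r)
      sample(setdiff(BASES, r), 1), "")
    germ <- data.frame(chrom = rep(chrom, length(gpos)), pos = gpos,
                       ref = seqchars[gpos],
                       alt = alt_of(seqchars[gpos]),
                       zygosity = ifelse(stats::runif(length(gpos)) <
                                           config$het_fraction, "het", "hom"),
                       stringsAsFactors = FALSE, row.names = NULL)
    som <- data.frame(chrom = rep(chrom, length(spos)), pos = spos,
                      ref = seqchars[spos],
                      alt = alt_of(seqchars[spos]),
                      cancer_fraction = rep(config$cancer_fraction,
                                            length(spos)),
                      stringsAsFactors = FALSE, row.names = NULL)
    structure(list(germline_sites = germ, somatic_sites = som),
              class = "ground_truth")
  })
}

#' Simulate a per-position pileup for one tissue
#'
#' Depth is Poisson(`depth_mean`) per position. At non-variant sites a
#' read is the reference base with probability `1 - error_rate`, else a
#' uniformly random other base. At germline sites the alt-read
#' probability is 0.5 (het) or 1.0 (hom) in every tissue; somatic sites
#' carry alt reads at their `cancer_fraction` only in cancer tissue.
#' Non-alt reads at variant sites follow the same error model.
#'
#' @param genome named character vector (single chromosome).
#' @param truth a `ground_truth` from [synth_truth()] (may have extra
#'   per-individual germline rows appended).
#' @param config a [sim_config()].
#' @param tissue one of `"blood"`, `"para"`, `"cancer"`.
#' @param seed_offset optional extra offset so different individuals get
#'   independent reads from the same truth.
#' @return pileup data.frame (`chrom`, `pos`, `ref`, `depth`,
#'   `A`, `C`, `G`, `T`), one row per genome position.
#' @export
synth_pileup <- function(genome, truth, config,
                         tissue = c("blood", "para", "cancer"),
                         seed_offset = 0L) {
  tissue <- match.arg(tissue)
  chrom <- names(genome)[1]
  ref <- strsplit(genome[[1]], "")[[1]]
  L <- length(ref)
  gs <- truth$germline_sites; ss <- truth$somatic_sites
  stopifnot(all(gs$pos >= 1), all(gs$pos <= L),
            all(ss$pos >= 1), all(ss$pos <= L))
  p_alt <- numeric(L)
  alt_base <- rep(NA_character_, L)
  if (nrow(gs) > 0) {
    p_alt[gs$pos] <- ifelse(gs$zygosity == "hom", 1.0, 0.5)
    alt_base[gs$pos] <- gs$alt
  }
  if (tissue == "cancer" && nrow(ss) > 0) {
    p_alt[ss$pos] <- ss$cancer_fraction
    alt_base[ss$pos] <- ss$alt
  }
  seed <- child_seed(config, paste0("pileup_", tissue)) +
    1000L * as.integer(seed_offset)
  withr::with_seed(seed, {
    depth <- stats::rpois(L, config$depth_mean)
    alt_n <- stats::rbinom(L, depth, p_alt)
    rem <- depth - alt_n
    err_n <- stats::rbinom(L, rem, config$error_rate)
    counts <- matrix(0L, nrow = L, ncol = 4,
                     dimnames = list(NULL, BASES))
    ref_idx <- match(ref, BASES)
    counts[cbind(seq_len(L), ref_idx)] <- rem - err_n
    which_alt <- which(alt_n > 0)
    if (length(which_alt)) {
      ai <- match(alt_base[which_alt], BASES)
      counts[cbind(which_alt, ai)] <- counts[cbind(which_alt, ai)] +
        alt_n[which_alt]
    }
    which_err <- which(err_n > 0)
    for (i in which_err) {
      others <- setdiff(1:4, ref_idx[i])
      split <- stats::rmultinom(1, err_n[i], rep(1 / 3, 3))[, 1]
      counts[i, others] <- counts[i, others] + split
    }
    data.frame(chrom = chrom, pos = seq_len(L), ref = ref, depth = depth,
               A = counts[, 1], C = counts[, 2], G = counts[, 3],
               T = counts[, 4], stringsAsFactors = FALSE)
  })
}

#' Simulate a scale-free interaction network with a planted module
#'
#' Grows a preferential-attachment graph (`ppi_attach` edges per new
#' node) over `ppi_nodes` genes, then overlays a planted module of
#' `planted_module_size` genes whose internal edge probability is 0.5.
#' Kept edges receive an `experiments` channel score drawn uniformly in
#' \[0.7, 0.95\] (other channels 0), so every edge passes the 0.700
#' combined-score threshold.
#'
#' @param config a [sim_config()].
#' @param gene_names pool of gene names (at least `ppi_nodes`).
#' @return List: `edges` (STRING-style data.frame with integer 0-1000
#'   scores), `nodes`, `planted_module_genes`.
#' @export
synth_ppi <- function(config, gene_names) {
  if (config$ppi_attach >= config$ppi_nodes) {
    stop("synth_ppi: ppi_attach must be < ppi_nodes")
  }
  if (config$ppi_nodes > length(gene_names)) {
    stop("synth_ppi: need at least ppi_nodes gene names")
  }
  if (config$planted_module_size > config$ppi_nodes) {
    stop("synth_ppi: planted module larger than network")
  }
  withr::with_seed(child_seed(config, "ppi"), {
    nodes <- sort(sample(gene_names, config$ppi_nodes))
    g <- igraph::sample_pa(config$ppi_nodes, m = config$ppi_attach,
                           directed = FALSE)
    el <- igraph::as_edgelist(g)
    a <- nodes[pmin(el[, 1], el[, 2])]
    b <- nodes[pmax(el[, 1], el[, 2])]
    module <- sort(sample(nodes, config$planted_module_size))
    if (length(module) >= 2) {
      pairs <- utils::combn(module, 2)
      keep <- stats::runif(ncol(pairs)) < 0.5
      a <- c(a, pairs[1, keep]); b <- c(b, pairs[2, keep])
    }
    key <- paste(pmin(a, b), pmax(a, b))
    first <- !duplicated(key)
    p1 <- pmin(a, b)[first]; p2 <- pmax(a, b)[first]
    ex <- as.integer(round(stats::runif(length(p1), 0.7, 0.95) * 1000))
    edges <- data.frame(protein1 = p1, protein2 = p2,
                        experiments = ex, databases = 0L, fusion = 0L,
                        combined_score = ex, stringsAsFactors = FALSE)
    list(edges = edges, nodes = nodes, planted_module_genes = module)
  })
}

#' Generate pathway gene sets overlapping the planted module
#'
#' Pathway 1 (`PI3K_AKT_LIKE`) contains every planted-module gene plus
#' random fillers; pathway 2 (`CANCER_LIKE`) contains ~80% of pathway 1
#' plus random genes; remaining pathways are random draws. Sizes are
#' kept within \[`min_size`, `max_size`\] (subject to the module fitting
#' in pathway 1).
#'
#' @param gene_names pool of gene names.
#' @param planted_module_genes planted-module gene names (may be empty,
#'   making pathway 1 purely random).
#' @param n_pathways total number of pathways (>= 2).
#' @param seed integer seed.
#' @param min_size,max_size pathway size bounds.
#' @return Named list of gene vectors (with `description` attributes),
#'   writable by [write_gmt()] and parseable by [load_gmt()].
#' @export
synth_pathways <- function(gene_names, planted_module_genes, n_pathways = 8,
                           seed = 1L, min_size = 20, max_size = 80) {
  if (n_pathways < 2) stop("synth_pathways: need n_pathways >= 2")
  max_size <- min(max_size, length(gene_names))
  min_size <- min(min_size, max_size)
  withr::with_seed(seed, {
    rand_set <- function(n) sort(sample(gene_names, n))
    target1 <- max(min_size, length(planted_module_genes) + 14)
    target1 <- min(target1, max_size)
    fillers <- setdiff(gene_names, planted_module_genes)
    n_fill <- max(0, target1 - length(planted_module_genes))
    p1 <- sort(c(planted_module_genes, sample(fillers, n_fill)))
    n_from_p1 <- round(0.8 * length(p1))
    p2_core <- sample(p1, n_from_p1)
    n_extra <- min(length(gene_names), max(0, min_size - n_from_p1) + 10)
    p2 <- sort(unique(c(p2_core, sample(gene_names, n_extra))))
    sets <- list(p1, p2)
    names(sets) <- c("PI3K_AKT_LIKE", "CANCER_LIKE")
    if (n_pathways > 2) {
      for (i in 3:n_pathways) {
        sets[[sprintf("PATHWAY_%02d", i)]] <-
          rand_set(sample(seq(min_size, max_size), 1))
      }
    }
    descs <- c("PI3K/AKT-type pathway (contains the planted module)",
               "pathways-in-cancer-type set (overlaps pathway 1)",
               rep("random pathway", max(0, n_pathways - 2)))
    for (i in seq_along(sets)) attr(sets[[i]], "description") <- descs[i]
    sets
  })
}

#' Simulate per-individual variant-gene sets for the two groups
#'
#' Familial individuals draw most of their variant-containing genes from
#' the planted module (mean `familial_module_genes`, sd 2, at least 16)
#' plus `familial_filler_genes` random genes; controls draw
#' `control_genes` genes uniformly from the pool. These sets mimic the
#' nonsynonymous gene sets the variant-calling and annotation stages
#' would produce.
#'
#' @param config a [sim_config()].
#' @param planted_module_genes planted module from [synth_ppi()].
#' @param gene_pool all gene names.
#' @return Named list of gene-name vectors; names are `FAMxx` /
#'   `CTLxx`, with a `label` attribute (`familial_patient` /
#'   `control`) on each element.
#' @export
synth_gene_sets <- function(config, planted_module_genes, gene_pool) {
  withr::with_seed(child_seed(config, "gene_sets"), {
    out <- list()
    for (i in seq_len(config$n_familial)) {
      n_mod <- round(stats::rnorm(1, config$familial_module_genes, 2))
      n_mod <- max(16, min(length(planted_module_genes), n_mod))
      genes <- c(sample(planted_module_genes, n_mod),
                 sample(setdiff(gene_pool, planted_module_genes),
                        config$familial_filler_genes))
      genes <- sort(unique(genes))
      attr(genes, "label") <- "familial_patient"
      out[[sprintf("FAM%02d", i)]] <- genes
    }
    for (i in seq_len(config$n_control)) {
      genes <- sort(sample(gene_pool, config$control_genes))
      attr(genes, "label") <- "control"
      out[[sprintf("CTL%02d", i)]] <- genes
    }
    out
  })
}

#' Plant one protein-altering variant in each requested gene
#'
#' For each gene, scans its coding positions in seeded-random order and
#' picks the first (position, alt) whose codon change is nonsynonymous
#' (or stop gain/loss), yielding germline sites that the annotation
#' stage will map back to exactly these genes.
#'
#' @param genome named character vector.
#' @param models gene-model data.frame.
#' @param genes gene names to hit.
#' @param seed integer seed.
#' @param zygosity zygosity given to every planted site (default
#'   `"hom"`, making recovery depth-limited only).
#' @return germline-site data.frame (`chrom`, `pos`, `ref`, `alt`,
#'   `zygosity`).
#' @export
plant_gene_variants <- function(genome, models, genes, seed,
                                zygosity = "hom") {
  withr::with_seed(seed, {
    rows <- list()
    for (g in genes) {
      model <- models[models$gene_name == g, , drop = FALSE][1, , drop = FALSE]
      if (nrow(model) == 0 || is.na(model$gene_name)) {
        stop("plant_gene_variants: gene not in models: ", g)
      }
      cpos <- sample(cds_positions(model))
      found <- FALSE
      for (p0 in cpos) {
        pos <- p0 + 1L
        ref <- substr(genome[[model$chrom]], pos, pos)
        for (alt in sample(setdiff(BASES, ref))) {
          ann <- consequence(list(chrom = model$chrom, pos = pos,
                                  ref = ref, alt = alt), models, genome)
          if (ann$consequence %in% c("nonsynonymous", "stop_gain",
                                     "stop_loss")) {
            rows[[length(rows) + 1]] <- data.frame(
              chrom = model$chrom, pos = pos, ref = ref, alt = alt,
              zygosity = zygosity, stringsAsFactors = FALSE)
            found <- TRUE
            break
          }
        }
        if (found) break
      }
      if (!found) stop("plant_gene_variants: no protein-altering site in ", g)
    }
    out <- do.call(rbind, rows)
    out[order(out$pos), , drop = FALSE]
  })
}

#' Simulate a case-control cohort with a designed exposure odds ratio
#'
#' @param config a [sim_config()]; uses `cohort_sizes` and
#'   `exposure_probs`.
#' @return List: `cohort` (data.frame `id`, `status`, `exposure`
#'   yes/no), `true_or`.
#' @export
synth_cohort <- function(config) {
  n_case <- config$cohort_sizes[1]; n_ctrl <- config$cohort_sizes[2]
  if (n_case <= 0 || n_ctrl <= 0) stop("synth_cohort: cohort sizes must be > 0")
  p <- config$exposure_probs
  withr::with_seed(child_seed(config, "cohort"), {
    status <- c(rep("case", n_case), rep("control", n_ctrl))
    probs <- c(rep(p[1], n_case), rep(p[2], n_ctrl))
    exposure <- ifelse(stats::runif(n_case + n_ctrl) < probs, "yes", "no")
    cohort <- data.frame(
      id = sprintf("S%05d", seq_len(n_case + n_ctrl)),
      status = status, exposure = exposure, stringsAsFactors = FALSE)
    list(cohort = cohort,
         true_or = (p[1] / (1 - p[1])) / (p[2] / (1 - p[2])))
  })
}

#' Write a complete synthetic input bundle to a directory
#'
#' Generates genome, refFlat, interaction edges, GMT, cohort CSV, and
#' per-individual pileups whose planted protein-altering variants hit
#' exactly the designed gene sets (familial individuals drawing from
#' the planted module). Familial individuals additionally receive a
#' cancer-tissue pileup with the shared somatic background sites.
#' Also writes `config.yaml`, a ready-to-run pipeline configuration.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, the pipeline-config list (see [run_cohort()]),
#'   with a `truth` attribute carrying the ground truth.
#' @export
simulate_all <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gen <- synth_genome(config)
  truth <- synth_truth(config, gen$genome)
  ppi <- synth_ppi(config, gen$models$gene_name)
  pathways <- synth_pathways(gen$models$gene_name,
                             ppi$planted_module_genes,
                             n_pathways = config$n_pathways,
                             seed = child_seed(config, "pathways"))
  gene_sets <- synth_gene_sets(config, ppi$planted_module_genes,
                               gen$models$gene_name)
  cohort <- synth_cohort(config)

  write_genome_fasta(gen$genome, file.path(outdir, "genome.fa"))
  write_refflat(gen$models, file.path(outdir, "genes.refflat"))
  write_string_edges(ppi$edges, file.path(outdir, "ppi_edges.tsv"))
  write_gmt(pathways, file.path(outdir, "pathways.gmt"))
  write_cohort_csv(cohort$cohort, file.path(outdir, "cohort.csv"))

  individuals <- list()
  ids <- names(gene_sets)
  for (j in seq_along(gene_sets)) {
    id <- ids[j]
    sites <- plant_gene_variants(gen$genome, gen$models, gene_sets[[j]],
                                 seed = child_seed(config, "individuals") + j)
    ind_truth <- list(germline_sites = sites,
                      somatic_sites = truth$somatic_sites)
    is_familial <- attr(gene_sets[[j]], "label") == "familial_patient"
    tissues <- if (is_familial) c("para", "cancer") else "blood"
    paths <- list()
    for (t in tissues) {
      pu <- synth_pileup(gen$genome, ind_truth, config, tissue = t,
                         seed_offset = j)
      f <- file.path(outdir, sprintf("%s_%s_pileup.tsv", tolower(id), t))
      write_pileup(pu, f)
      paths[[t]] <- basename(f)
    }
    paths$label <- if (is_familial) "familial_patient" else "control"
    individuals[[id]] <- paths
  }

  pipeline_cfg <- list(
    seed = config$seed,
    params = list(alpha = 0.01, min_depth = 10, score_threshold = 0.700,
                  channels = as.list(PPI_CHANNELS), k_top = 10,
                  pi3k_min = 15, cancer_min = 10, fraction_min = 0.60,
                  pi3k_id = "PI3K_AKT_LIKE", cancer_id = "CANCER_LIKE"),
    paths = list(genome = "genome.fa", refflat = "genes.refflat",
                 edges = "ppi_edges.tsv", gmt = "pathways.gmt",
                 cohort = "cohort.csv", individuals = individuals),
    epi = list(contrasts = list(list(field = "exposure", level = "yes",
                                     reference = "no"))))
  yaml::write_yaml(pipeline_cfg, file.path(outdir, "config.yaml"))
  attr(pipeline_cfg, "truth") <-
    list(ground_truth = truth, gene_sets = gene_sets,
         planted_module_genes = ppi$planted_module_genes,
         true_or = cohort$true_or)
  invisible(pipeline_cfg)
}
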
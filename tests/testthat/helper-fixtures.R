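# Shared fixture builders. Everything is generated in code; no files.

# A pileup row with explicit base counts (depth defaults to their sum).
pileup_row <- function(pos, ref, A = 0, C = 0, G = 0, T = 0,
                       chrom = "chr1", depth = A + C + G + T) {
  data.frame(chrom = chrom, pos = pos, ref = ref, depth = depth,
             A = A, C = C, G = G, T = T, stringsAsFactors = FALSE)
}

# A pileup of `n` pure-reference positions plus optional variant rows.
ref_pileup <- function(n, depth = 30, ref = "A", chrom = "chr1") {
  if (n == 0) {
    return(pileup_row(1, "A", A = 1)[0, , drop = FALSE])
  }
  do.call(rbind, lapply(seq_len(n), function(i) {
    counts <- c(A = 0, C = 0, G = 0, T = 0)
    counts[ref] <- depth
    pileup_row(i, ref, counts["A"], counts["C"], counts["G"], counts["T"],
               chrom = chrom)
  }))
}

# Single-exon plus-strand gene: CDS covers [start, start + 3*n_codons).
toy_model <- function(gene = "G1", chrom = "chr1", strand = "+",
                      start = 0L, n_codons = 3L) {
  len <- 3L * n_codons
  df <- data.frame(gene_name = gene, transcript_id = paste0(gene, ".t1"),
                   chrom = chrom, strand = strand,
                   tx_start = start, tx_end = start + len,
                   cds_start = start, cds_end = start + len,
                   exon_count = 1L, stringsAsFactors = FALSE)
  df$exon_starts <- list(start)
  df$exon_ends <- list(start + len)
  df$codable <- TRUE
  df
}

# Edge table where every edge has a single experiments score (0-1 scale).
edge_table <- function(pairs, score = 0.9) {
  if (length(pairs) == 0) {
    return(data.frame(protein1 = character(), protein2 = character(),
                      experiments = integer(), databases = integer(),
                      fusion = integer(), combined_score = integer(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, pairs)
  s <- as.integer(round(rep_len(score, nrow(m)) * 1000))
  data.frame(protein1 = m[, 1], protein2 = m[, 2],
             experiments = s, databases = 0L, fusion = 0L,
             combined_score = s, stringsAsFactors = FALSE)
}

# Tiny risk_features stand-in.
rf <- function(id, pi3k, cancer, fraction = 0, label = "unknown") {
  structure(list(individual_id = id, n_pi3k_genes = pi3k,
                 n_cancer_pathway_genes = cancer, main_fraction = fraction,
                 n_main = 0, label = label), class = "risk_features")
}

# Random simple graph as an igraph with vertex names and its adjacency.
random_named_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    adj <- matrix(stats::runif(n * n) < p, n, n)
    adj[lower.tri(adj, diag = TRUE)] <- FALSE
    adj <- adj | t(adj)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
    list(graph = g, adj = adj)
  })
}

# expand printed 2x2 counts into one record per individual
expand_records <- function(exposed_cases, exposed_controls,
                           unexposed_cases, unexposed_controls,
                           field = "exposure", exposed = "yes",
                           reference = "no") {
  df <- data.frame(
    status = c(rep("case", exposed_cases + unexposed_cases),
               rep("control", exposed_controls + unexposed_controls)),
    stringsAsFactors = FALSE)
  df[[field]] <- c(rep(exposed, exposed_cases),
                   rep(reference, unexposed_cases),
                   rep(exposed, exposed_controls),
                   rep(reference, unexposed_controls))
  df$id <- sprintf("I%05d", seq_len(nrow(df)))
  df
}

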
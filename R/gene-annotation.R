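#' refFlat gene models and coding-consequence annotation
#'
#' @description
#' Gene models are parsed from UCSC refFlat text (11 tab-separated
#' columns, 0-based half-open coordinates). Variants — 1-based pileup
#' coordinates, converted internally — are placed into the coding
#' sequence of every overlapping codable transcript, the affected codon
#' is translated with the standard genetic code (reverse-complementing on
#' the minus strand), and the per-transcript consequences are collapsed
#' to the most severe one. The nonsynonymous subset (including stop
#' gain/loss) feeds all network analyses.
#'
#' @name gene_annotation
NULL

CONSEQ_SEVERITY <- c(noncoding = 0, synonymous = 1, nonsynonymous = 2,
                     stop_gain = 3, stop_loss = 3)

#' Parse refFlat gene models
#'
#' @param text refFlat content as a character vector of lines, a single
#'   string with embedded newlines, or a file path.
#' @return data.frame with one row per transcript: `gene_name`,
#'   `transcript_id`, `chrom`, `strand`, `tx_start`, `tx_end`,
#'   `cds_start`, `cds_end`, `exon_count` (all coordinates 0-based
#'   half-open), list-columns `exon_starts`/`exon_ends`, and a logical
#'   `codable` flag (FALSE when the concatenated CDS length is not a
#'   multiple of 3; such models are skipped by the annotator, with a
#'   warning at parse time).
#' @export
parse_refflat <- function(text) {
  lines <- as_text_lines(text)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(gene_name = character(), transcript_id = character(),
                      chrom = character(), strand = character(),
                      tx_start = integer(), tx_end = integer(),
                      cds_start = integer(), cds_end = integer(),
                      exon_count = integer(), stringsAsFactors = FALSE)
  empty$exon_starts <- list(); empty$exon_ends <- list()
  empty$codable <- logical()
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf != 11L)) {
    stop(sprintf("parse_refflat: line %d has %d columns, expected 11",
                 which(nf != 11L)[1], nf[nf != 11L][1]))
  }
  parse_coord_list <- function(s, line) {
    xs <- strsplit(s, ",", fixed = TRUE)[[1]]
    xs <- xs[nzchar(xs)]                      # tolerate trailing comma
    out <- suppressWarnings(as.integer(xs))
    if (anyNA(out)) stop("parse_refflat: non-numeric coordinate on line ", line)
    out
  }
  num <- function(i, col) {
    out <- suppressWarnings(as.integer(vapply(fields, `[`, "", col)))
    if (anyNA(out)) {
      stop("parse_refflat: non-numeric coordinate on line ",
           which(is.na(out))[1])
    }
    out
  }
  n <- length(fields)
  models <- data.frame(
    gene_name = vapply(fields, `[`, "", 1),
    transcript_id = vapply(fields, `[`, "", 2),
    chrom = vapply(fields, `[`, "", 3),
    strand = vapply(fields, `[`, "", 4),
    tx_start = num(n, 5), tx_end = num(n, 6),
    cds_start = num(n, 7), cds_end = num(n, 8),
    exon_count = num(n, 9), stringsAsFactors = FALSE)
  models$exon_starts <- lapply(seq_len(n), function(i)
    parse_coord_list(fields[[i]][10], i))
  models$exon_ends <- lapply(seq_len(n), function(i)
    parse_coord_list(fields[[i]][11], i))
  bad_exons <- vapply(seq_len(n), function(i) {
    length(models$exon_starts[[i]]) != models$exon_count[i] ||
      length(models$exon_ends[[i]]) != models$exon_count[i]
  }, TRUE)
  if (any(bad_exons)) {
    stop("parse_refflat: exon list length != exonCount on line ",
         which(bad_exons)[1])
  }
  models$codable <- vapply(seq_len(n), function(i) {
    cds_len <- sum(pmax(0, pmin(models$exon_ends[[i]], models$cds_end[i]) -
                          pmax(models$exon_starts[[i]], models$cds_start[i])))
    cds_len > 0 && cds_len %% 3 == 0
  }, TRUE)
  if (any(!models$codable)) {
    warning(sprintf("parse_refflat: %d model(s) flagged non-codable (CDS length not a multiple of 3)",
                    sum(!models$codable)))
  }
  models
}

as_text_lines <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    return(readLines(text))
  }
  unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
}

# Genomic positions (0-based) of the coding sequence of one model, in
# translation order (ascending for +, descending for -).
cds_positions <- function(model) {
  starts <- pmax(model$exon_starts[[1]], model$cds_start)
  ends <- pmin(model$exon_ends[[1]], model$cds_end)
  keep <- ends > starts
  pos <- unlist(lapply(which(keep), function(i)
    seq(starts[i], ends[i] - 1L)), use.names = FALSE)
  if (identical(model$strand, "-")) rev(pos) else pos
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Annotate the coding consequence of a variant
#'
#' @param variant list or one-row data.frame with `chrom`, `pos`
#'   (1-based), `ref`, `alt`.
#' @param models gene-model data.frame from [parse_refflat()].
#' @param genome named character vector of chromosome sequences.
#' @return List: `key`, `gene_name` (NA when noncoding with no gene),
#'   `consequence` in `noncoding`/`synonymous`/`nonsynonymous`/
#'   `stop_gain`/`stop_loss` (most severe over overlapping codable
#'   transcripts), plus `ref_aa`/`alt_aa` for coding hits.
#' @export
consequence <- function(variant, models, genome) {
  v <- as.list(variant)
  gpos <- v$pos - 1L                       # to 0-based
  chrom_seq <- genome[[v$chrom]]
  if (is.null(chrom_seq)) stop("consequence: chromosome not in genome: ", v$chrom)
  genome_ref <- substr(chrom_seq, v$pos, v$pos)
  if (genome_ref != v$ref) {
    stop(sprintf("consequence: reference mismatch at %s:%d (pileup %s, genome %s)",
                 v$chrom, v$pos, v$ref, genome_ref))
  }
  overlapping <- models[models$chrom == v$chrom &
                          models$tx_start <= gpos & gpos < models$tx_end, ,
                        drop = FALSE]
  best <- list(consequence = "noncoding", gene_name = NA_character_,
               ref_aa = NA_character_, alt_aa = NA_character_)
  if (nrow(overlapping) > 0) best$gene_name <- overlapping$gene_name[1]
  for (i in seq_len(nrow(overlapping))) {
    model <- overlapping[i, , drop = FALSE]
    if (!model$codable) next
    cpos <- cds_positions(model)
    idx <- match(gpos, cpos)
    if (is.na(idx)) next                    # intronic / UTR for this model
    codon_i <- (idx - 1L) %/% 3L
    codon_pos <- cpos[(codon_i * 3L + 1L):(codon_i * 3L + 3L)]
    bases <- substring(chrom_seq, codon_pos + 1L, codon_pos + 1L)
    if (identical(model$strand, "-")) bases <- unname(COMPLEMENT[bases])
    ref_codon <- paste(bases, collapse = "")
    within <- idx - codon_i * 3L            # 1..3
    alt_base <- if (identical(model$strand, "-")) COMPLEMENT[[v$alt]] else v$alt
    alt_bases <- bases
    alt_bases[within] <- alt_base
    alt_codon <- paste(alt_bases, collapse = "")
    gc <- Biostrings::GENETIC_CODE
    ref_aa <- unname(gc[ref_codon]); alt_aa <- unname(gc[alt_codon])
    cons <- if (ref_aa == alt_aa) "synonymous"
      else if (alt_aa == "*") "stop_gain"
      else if (ref_aa == "*") "stop_loss"
      else "nonsynonymous"
    if (CONSEQ_SEVERITY[cons] > CONSEQ_SEVERITY[best$consequence]) {
      best <- list(consequence = cons, gene_name = model$gene_name,
                   ref_aa = ref_aa, alt_aa = alt_aa)
    }
  }
  c(list(key = paste0(v$chrom, ":", v$pos, ":", v$ref, ">", v$alt)), best)
}

#' Annotate many variants at once
#'
#' @param calls variant data.frame (or key vector via
#'   [parse_variant_keys()]).
#' @inheritParams consequence
#' @return data.frame with columns `key`, `gene_name`, `consequence`,
#'   `ref_aa`, `alt_aa`.
#' @export
annotate_variants <- function(calls, models, genome) {
  if (is.character(calls)) calls <- parse_variant_keys(calls)
  rows <- lapply(seq_len(nrow(calls)), function(i)
    consequence(calls[i, , drop = FALSE], models, genome))
  data.frame(
    key = vapply(rows, `[[`, "", "key"),
    gene_name = vapply(rows, `[[`, "", "gene_name"),
    consequence = vapply(rows, `[[`, "", "consequence"),
    ref_aa = vapply(rows, `[[`, "", "ref_aa"),
    alt_aa = vapply(rows, `[[`, "", "alt_aa"),
    stringsAsFactors = FALSE)
}

#' Genes carrying protein-altering variants
#'
#' @param annotated data.frame from [annotate_variants()].
#' @return sorted unique gene names whose consequence is nonsynonymous,
#'   stop_gain or stop_loss.
#' @export
nonsynonymous_genes <- function(annotated) {
  keep <- annotated$consequence %in% c("nonsynonymous", "stop_gain", "stop_loss")
  sort(unique(annotated$gene_name[keep & !is.na(annotated$gene_name)]))
}
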
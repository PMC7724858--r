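#' Readers and writers for the pipeline's plain-text exchange formats
#'
#' @description
#' Every intermediate artifact is written in a documented standard format
#' and can be re-read by its own parser: FASTA genomes (via Biostrings),
#' pileup TSV, refFlat gene models, STRING-style interaction-edge TSV
#' (integer 0-1000 channel scores), GMT gene sets, cohort CSV, and a
#' minimal VCF 4.2 for variant calls.
#'
#' @name germnet_io
NULL

#' Write a genome to FASTA
#' @param genome named character vector of sequences (names become record
#'   ids), or a single unnamed sequence written as `chrS`.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.null(names(genome))) names(genome) <- paste0("chrS", seq_along(genome))
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, filepath = path, width = 70)
  invisible(path)
}

#' Read a FASTA genome as a named character vector
#' @param path FASTA file.
#' @export
read_genome_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write a pileup table as TSV
#'
#' Columns: CHROM, POS (1-based), REF, DEPTH, A, C, G, T.
#' @param pileup pileup data.frame.
#' @param path output file.
#' @export
write_pileup <- function(pileup, path) {
  out <- pileup[, c("chrom", "pos", "ref", "depth", "A", "C", "G", "T")]
  names(out) <- c("CHROM", "POS", "REF", "DEPTH", "A", "C", "G", "T")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a pileup TSV written by [write_pileup()]
#' @param path pileup TSV file.
#' @export
read_pileup <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character",
                                         "integer", "integer", "integer",
                                         "integer", "integer"))
  names(df) <- c("chrom", "pos", "ref", "depth", "A", "C", "G", "T")
  df
}

#' Write gene models in refFlat format
#'
#' Eleven tab-separated columns with comma-terminated exon coordinate
#' lists, 0-based half-open (UCSC convention).
#' @param models gene-model data.frame as produced by [synth_genome()] or
#'   [parse_refflat()].
#' @param path output file.
#' @export
write_refflat <- function(models, path) {
  lines <- vapply(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    paste(m$gene_name, m$transcript_id, m$chrom, m$strand,
          m$tx_start, m$tx_end, m$cds_start, m$cds_end, m$exon_count,
          paste0(paste(m$exon_starts[[1]], collapse = ","), ","),
          paste0(paste(m$exon_ends[[1]], collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write an interaction-edge table in STRING-style TSV
#'
#' Columns: protein1, protein2, experiments, databases, fusion,
#' combined_score; scores are integers on the 0-1000 scale.
#' @param edges edge data.frame.
#' @param path output file.
#' @export
write_string_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a STRING-style interaction-edge TSV
#' @param path edge TSV with header
#'   `protein1 protein2 experiments databases fusion combined_score`.
#' @export
read_string_edges <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein1", "protein2")
  if (!all(need %in% names(df))) {
    stop("read_string_edges: missing protein1/protein2 columns")
  }
  df
}

#' Write gene sets in GMT format
#' @param pathways named list of character vectors (names are pathway
#'   ids); descriptions taken from the `description` attribute of each
#'   element, defaulting to `"na"`.
#' @param path output file.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(id) {
    genes <- pathways[[id]]
    desc <- attr(genes, "description")
    if (is.null(desc)) desc <- "na"
    paste(c(id, desc, as.character(genes)), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a case-control cohort table as CSV
#' @param cohort data.frame with `id`, `status` and exposure columns.
#' @param path output file.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a case-control cohort CSV
#'
#' Requires a `status` column with values in {case, control}; unknown
#' status values are rejected.
#' @param path CSV file.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"status" %in% names(df)) stop("cohort file needs a 'status' column")
  bad <- setdiff(unique(df$status), c("case", "control"))
  if (length(bad)) {
    stop("cohort file: unknown status value(s): ", paste(bad, collapse = ", "))
  }
  df
}

#' Write variant calls as minimal VCF 4.2
#'
#' One record per call with INFO fields `DP` (depth), `AC` (alt reads)
#' and `FETP` (Fisher exact test p-value); zygosity is carried as a
#' `GT`-free `ZYG` INFO field to keep the file site-only.
#'
#' @param calls sorted variant data.frame from [call_sample()].
#' @param reference reference genome name for the `##reference` header.
#' @param path output file.
#' @export
write_vcf <- function(calls, reference, path) {
  if (nrow(calls) > 0) {
    o <- order(calls$chrom, calls$pos)
    if (any(o != seq_len(nrow(calls)))) {
      stop("write_vcf: calls must be sorted by (chrom, pos)")
    }
  }
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##reference=", reference),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alt read count\">",
    "##INFO=<ID=FETP,Number=1,Type=Float,Description=\"Fisher exact test p-value\">",
    "##INFO=<ID=ZYG,Number=1,Type=String,Description=\"Zygosity call (het/hom)\">",
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"germline/somatic/unclassified\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  records <- character(0)
  if (nrow(calls) > 0) {
    info <- sprintf("DP=%d;AC=%d;FETP=%s;ZYG=%s;ORIGIN=%s",
                    calls$depth, calls$alt_count,
                    format(calls$p_value, digits = 6, scientific = TRUE,
                           trim = TRUE),
                    calls$zygosity, calls$origin)
    records <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                       calls$chrom, calls$pos, calls$ref, calls$alt, info)
  }
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read a minimal VCF written by [write_vcf()]
#' @param path VCF file.
#' @return variant data.frame in [call_sample()] layout.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines)]
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      alt_count = integer(), depth = integer(),
                      p_value = numeric(), zygosity = character(),
                      origin = character(), stringsAsFactors = FALSE)
  if (length(body) == 0) return(empty)
  fields <- strsplit(body, "\t", fixed = TRUE)
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  info <- vapply(fields, `[`, "", 8)
  data.frame(
    chrom = vapply(fields, `[`, "", 1),
    pos = as.integer(vapply(fields, `[`, "", 2)),
    ref = vapply(fields, `[`, "", 4),
    alt = vapply(fields, `[`, "", 5),
    alt_count = as.integer(info_get(info, "AC")),
    depth = as.integer(info_get(info, "DP")),
    p_value = as.numeric(info_get(info, "FETP")),
    zygosity = info_get(info, "ZYG"),
    origin = info_get(info, "ORIGIN"),
    stringsAsFactors = FALSE)
}
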
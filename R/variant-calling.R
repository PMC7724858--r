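#' Fisher-exact SNV calling from per-position pileups
#'
#' @description
#' Variants are called position by position from base-count pileups. For
#' each position with depth >= `min_depth`, the most frequent non-reference
#' base (count `a` out of depth `d`) is tested with a one-sided Fisher
#' exact test of the 2x2 table `[[a, d - a], [0, d]]` — the observed sample
#' against an ideal all-reference sample of the same depth, encoding the
#' null hypothesis that every read at the position matches the reference.
#' The position is called a variant when p < `alpha`.
#'
#' This table construction is a documented reconstruction: the published
#' pipelines this mirrors state the null ("all nucleotides identical to
#' the reference") and the threshold, but not the table; the chosen
#' encoding is the most literal one and has a closed-form hypergeometric
#' tail.
#'
#' @name variant_calling
NULL

BASES <- c("A", "C", "G", "T")

#' One-sided Fisher p-value for an alt count at a given depth
#'
#' Closed form of `fisher_exact([[a, d-a], [0, d]], "one_sided")`:
#' the hypergeometric upper tail P(X >= a) with population `a` alt +
#' `2d - a` ref reads and `d` draws. Vectorised over `alt` and `depth`.
#'
#' @param alt alternative-base read count(s).
#' @param depth total read depth(s).
#' @return p-value(s).
#' @export
snv_p_value <- function(alt, depth) {
  stopifnot(all(alt >= 0), all(alt <= depth))
  stats::phyper(alt - 1, alt, 2 * depth - alt, depth, lower.tail = FALSE)
}

#' Call an SNV at a single pileup position
#'
#' @param column list or one-row data.frame with fields `chrom`, `pos`
#'   (1-based), `ref`, `depth` and base counts `A`, `C`, `G`, `T`.
#' @param alpha significance threshold (default 0.01).
#' @param min_depth minimum depth to consider a position (default 10).
#' @return A one-row variant data.frame (`chrom`, `pos`, `ref`, `alt`,
#'   `alt_count`, `depth`, `p_value`, `zygosity`, `origin`), or `NULL`
#'   if the position is filtered or not significant. Zygosity is `hom`
#'   when the alt fraction is >= 0.85, otherwise `het`; origin starts
#'   `unclassified`.
#' @export
call_snv <- function(column, alpha = 0.01, min_depth = 10) {
  stopifnot(alpha > 0, alpha < 1)
  col <- as.list(column)
  counts <- as.integer(col[BASES])
  if (anyNA(counts) || sum(counts) != col$depth) {
    stop(sprintf("call_snv: base counts do not sum to depth at %s:%d",
                 col$chrom, col$pos))
  }
  df <- data.frame(chrom = col$chrom, pos = col$pos, ref = col$ref,
                   depth = col$depth, A = counts[1], C = counts[2],
                   G = counts[3], T = counts[4],
                   stringsAsFactors = FALSE)
  res <- call_sample(df, alpha = alpha, min_depth = min_depth)
  if (nrow(res) == 0) NULL else res
}

#' Call SNVs across a whole pileup table
#'
#' Applies the per-position Fisher test to every row of a pileup table.
#' The table must be sorted by (chrom, pos) with no duplicate positions.
#'
#' @param pileup data.frame with columns `chrom`, `pos`, `ref`, `depth`,
#'   `A`, `C`, `G`, `T`.
#' @inheritParams call_snv
#' @return data.frame of calls (possibly 0 rows), sorted by (chrom, pos),
#'   with columns `chrom`, `pos`, `ref`, `alt`, `alt_count`, `depth`,
#'   `p_value`, `zygosity`, `origin`.
#' @export
call_sample <- function(pileup, alpha = 0.01, min_depth = 10) {
  stopifnot(alpha > 0, alpha < 1)
  required <- c("chrom", "pos", "ref", "depth", BASES)
  if (!all(required %in% names(pileup))) {
    stop("call_sample: pileup must have columns ",
         paste(required, collapse = ", "))
  }
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      alt_count = integer(), depth = integer(),
                      p_value = numeric(), zygosity = character(),
                      origin = character(), stringsAsFactors = FALSE)
  if (nrow(pileup) == 0) return(empty)
  o <- order(pileup$chrom, pileup$pos)
  if (any(o != seq_len(nrow(pileup)))) {
    stop("call_sample: pileup must be sorted by (chrom, pos)")
  }
  if (anyDuplicated(paste(pileup$chrom, pileup$pos))) {
    stop("call_sample: duplicate positions in pileup")
  }
  cm <- as.matrix(pileup[, BASES])
  if (any(rowSums(cm) != pileup$depth)) {
    stop("call_sample: base counts inconsistent with depth")
  }
  keep <- pileup$depth >= min_depth
  if (!any(keep)) return(empty)
  cm <- cm[keep, , drop = FALSE]
  sub <- pileup[keep, , drop = FALSE]
  # mask the reference base, then take the most frequent remaining base;
  # ties resolved in fixed A < C < G < T order by max.col("first")
  ref_idx <- match(sub$ref, BASES)
  if (anyNA(ref_idx)) stop("call_sample: reference base not in {A,C,G,T}")
  cm[cbind(seq_len(nrow(cm)), ref_idx)] <- -1L
  alt_idx <- max.col(cm, ties.method = "first")
  alt_count <- cm[cbind(seq_len(nrow(cm)), alt_idx)]
  p <- snv_p_value(alt_count, sub$depth)
  sig <- alt_count > 0 & p < alpha
  if (!any(sig)) return(empty)
  out <- data.frame(
    chrom = sub$chrom[sig], pos = sub$pos[sig], ref = sub$ref[sig],
    alt = BASES[alt_idx[sig]],
    alt_count = as.integer(alt_count[sig]),
    depth = as.integer(sub$depth[sig]),
    p_value = p[sig],
    zygosity = ifelse(alt_count[sig] / sub$depth[sig] >= 0.85, "hom", "het"),
    origin = "unclassified", stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Variant keys: `chrom:pos:ref>alt` identifiers for set operations
#'
#' @param calls variant data.frame as returned by [call_sample()].
#' @return character vector of keys.
#' @export
variant_keys <- function(calls) {
  if (nrow(calls) == 0) return(character())
  paste0(calls$chrom, ":", calls$pos, ":", calls$ref, ">", calls$alt)
}

#' Split variant keys back into their fields
#'
#' @param keys character vector of `chrom:pos:ref>alt` keys.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
parse_variant_keys <- function(keys) {
  if (length(keys) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- regmatches(keys, regexec("^(.+):(\\d+):([ACGT])>([ACGT])$", keys))
  bad <- vapply(parts, length, 1L) != 5L
  if (any(bad)) stop("malformed variant key: ", keys[bad][1])
  data.frame(chrom = vapply(parts, `[`, "", 2),
             pos = as.integer(vapply(parts, `[`, "", 3)),
             ref = vapply(parts, `[`, "", 4),
             alt = vapply(parts, `[`, "", 5),
             stringsAsFactors = FALSE)
}

#' Germline variant set from a blood or para-cancer sample
#'
#' Calls from a non-tumor sample are, by definition, germline: positions
#' where the inherited sequence differs from the reference genome.
#'
#' @param calls variant data.frame from a blood or para-cancer pileup.
#' @return character vector of variant keys (sorted, unique).
#' @export
germline_set <- function(calls) {
  sort(unique(variant_keys(calls)))
}

#' Somatic variant set by coverage-gated tumor-normal subtraction
#'
#' A variant is somatic when it is called in the tumor sample, not called
#' in the matched para-cancer (normal) sample, and the para-cancer pileup
#' has depth >= `min_para_depth` at the position — so "absent in normal"
#' is evidenced by adequate coverage rather than a coverage gap.
#'
#' @param cancer_calls,para_calls variant data.frames from the same
#'   individual's tumor and matched normal samples.
#' @param para_pileup the normal sample's pileup table (for depth lookup).
#' @param min_para_depth minimum normal depth required to accept absence.
#' @return character vector of somatic variant keys (sorted, unique).
#' @export
somatic_set <- function(cancer_calls, para_calls, para_pileup,
                        min_para_depth = 10) {
  if (is.null(para_pileup) ||
      !all(c("chrom", "pos", "depth") %in% names(para_pileup))) {
    stop("somatic_set: para-cancer pileup with depth information required")
  }
  ck <- variant_keys(cancer_calls)
  pk <- variant_keys(para_calls)
  cand <- cancer_calls[!(ck %in% pk), , drop = FALSE]
  if (nrow(cand) == 0) return(character())
  idx <- match(paste(cand$chrom, cand$pos),
               paste(para_pileup$chrom, para_pileup$pos))
  para_depth <- ifelse(is.na(idx), 0L, para_pileup$depth[idx])
  sort(unique(variant_keys(cand[para_depth >= min_para_depth, , drop = FALSE])))
}

#' Intersection of germline variant sets across individuals
#'
#' @param sets list of one or more variant-key character vectors.
#' @return character vector: keys present in every set (sorted).
#' @export
shared_germline <- function(sets) {
  if (!is.list(sets) || length(sets) == 0) {
    stop("shared_germline: need a non-empty list of key sets")
  }
  sort(Reduce(intersect, sets))
}

#' Cross-reference variants against a local classification catalog
#'
#' Left-joins variant keys against a catalog table (columns `chrom`,
#' `pos`, `ref`, `alt`, `classification`) and summarises how many
#' variants carry a non-"benign" classification and what fraction were
#' found in the catalog at all. Stands in for online clinical-database
#' lookups, which are out of scope.
#'
#' @param keys character vector of variant keys.
#' @param catalog data.frame catalog, or a path to a tab-separated file
#'   with the columns above (malformed lines are skipped with a warning).
#' @return List: `annotations` (data.frame key/classification, NA when
#'   absent), `n_non_benign`, `present_fraction`.
#' @export
crossref_catalog <- function(keys, catalog) {
  if (is.character(catalog) && length(catalog) == 1) {
    catalog <- read_catalog(catalog)
  }
  need <- c("chrom", "pos", "ref", "alt", "classification")
  if (!all(need %in% names(catalog))) {
    stop("crossref_catalog: catalog needs columns ",
         paste(need, collapse = ", "))
  }
  cat_keys <- paste0(catalog$chrom, ":", catalog$pos, ":",
                     catalog$ref, ">", catalog$alt)
  idx <- match(keys, cat_keys)
  cls <- ifelse(is.na(idx), NA_character_, catalog$classification[idx])
  present <- !is.na(cls)
  list(annotations = data.frame(key = keys, classification = cls,
                                stringsAsFactors = FALSE),
       n_non_benign = sum(present & tolower(cls) != "benign", na.rm = TRUE),
       present_fraction = if (length(keys)) mean(present) else 0)
}

read_catalog <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, 1L) >= 5L
  if (any(!ok)) {
    warning(sprintf("crossref_catalog: skipped %d malformed catalog line(s)",
                    sum(!ok)))
  }
  fields <- fields[ok]
  data.frame(
    chrom = vapply(fields, `[`, "", 1),
    pos = as.integer(vapply(fields, `[`, "", 2)),
    ref = vapply(fields, `[`, "", 3),
    alt = vapply(fields, `[`, "", 4),
    classification = vapply(fields, `[`, "", 5),
    stringsAsFactors = FALSE)
}
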
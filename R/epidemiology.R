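#' Case-control contingency tables and crude odds-ratio reports
#'
#' @description
#' Builds exposure-by-status 2x2 tables from a cohort table (one record
#' per individual with a `status` column and named categorical exposure
#' fields) and reports crude odds ratios with Woolf 95% confidence
#' intervals, including reference rows printed as OR 1.00. Only crude
#' (unadjusted) odds ratios are computed: covariate-adjusted estimates
#' require individual-level covariates that are out of scope here.
#' Stratified tables (e.g. by histology) compare each stratum against a
#' named reference stratum.
#'
#' @name epidemiology
NULL

#' Build a 2x2 exposure-by-status table from cohort records
#'
#' Records whose exposure value is neither `exposed_level` nor
#' `reference_level` are excluded.
#'
#' @param records cohort data.frame with `status` (case/control) and the
#'   exposure field.
#' @param exposure_field name of the exposure column.
#' @param exposed_level,reference_level the two levels contrasted.
#' @return a [contingency_2x2()].
#' @export
tabulate_exposure <- function(records, exposure_field, exposed_level,
                              reference_level) {
  if (!exposure_field %in% names(records)) {
    stop("tabulate_exposure: no such exposure field: ", exposure_field)
  }
  v <- as.character(records[[exposure_field]])
  status <- records$status
  cells <- c(
    sum(v == exposed_level & status == "case"),
    sum(v == exposed_level & status == "control"),
    sum(v == reference_level & status == "case"),
    sum(v == reference_level & status == "control"))
  if (sum(cells) == 0) {
    # all-zero table: report with full Haldane correction downstream
    return(structure(as.list(rep(0L, 4)),
                     names = c("exposed_cases", "exposed_controls",
                               "unexposed_cases", "unexposed_controls"),
                     class = "contingency_2x2"))
  }
  contingency_2x2(cells[1], cells[2], cells[3], cells[4])
}

#' Crude odds-ratio report over a list of exposure contrasts
#'
#' One row per contrast; for each contrast the reference level is also
#' reported as a row with OR 1.00 (the conventional table layout).
#' Odds ratios and interval bounds are rounded to 2 decimals in the
#' report only; full-precision values are kept alongside.
#'
#' @param records cohort data.frame.
#' @param contrasts list of lists/vectors with elements `field`, `level`,
#'   `reference`.
#' @return data.frame: `field`, `level`, `cases`, `controls`,
#'   `odds_ratio`, `ci_low`, `ci_high` (2-dp), `or_full`, `ci_low_full`,
#'   `ci_high_full`, `corrected`, `is_reference`.
#' @export
or_table <- function(records, contrasts) {
  rows <- list()
  for (ct in contrasts) {
    ct <- as.list(ct)
    tab <- tabulate_exposure(records, ct$field, ct$level, ct$reference)
    res <- woolf_or(tab)
    rows[[length(rows) + 1]] <- data.frame(
      field = ct$field, level = ct$reference,
      cases = tab$unexposed_cases, controls = tab$unexposed_controls,
      odds_ratio = 1.00, ci_low = NA_real_, ci_high = NA_real_,
      or_full = 1, ci_low_full = NA_real_, ci_high_full = NA_real_,
      corrected = FALSE, is_reference = TRUE, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      field = ct$field, level = ct$level,
      cases = tab$exposed_cases, controls = tab$exposed_controls,
      odds_ratio = round(res$odds_ratio, 2),
      ci_low = round(res$ci_low, 2), ci_high = round(res$ci_high, 2),
      or_full = res$odds_ratio, ci_low_full = res$ci_low,
      ci_high_full = res$ci_high,
      corrected = res$corrected, is_reference = FALSE,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Crude odds ratios of an exposure across strata
#'
#' Within the subset of records belonging to `stratum` or
#' `reference_stratum`, builds the 2x2 table of exposure (level
#' `exposed_level` vs `reference_level`) by stratum membership (stratum
#' records as "cases") and reports the crude OR per non-reference
#' stratum. Strata with zero records are skipped with a warning.
#'
#' @param records cohort data.frame.
#' @param stratum_field column defining the strata.
#' @param reference_stratum stratum treated as the comparison group.
#' @param exposure_field exposure column.
#' @param exposed_level,reference_level exposure levels contrasted
#'   (defaults "yes"/"no").
#' @return data.frame with one row per non-reference stratum:
#'   `stratum`, cell counts, `odds_ratio`, `ci_low`, `ci_high` (2-dp)
#'   and full-precision columns.
#' @export
stratified_or <- function(records, stratum_field, reference_stratum,
                          exposure_field, exposed_level = "yes",
                          reference_level = "no") {
  if (!stratum_field %in% names(records)) {
    stop("stratified_or: no such stratum field: ", stratum_field)
  }
  strata <- setdiff(unique(as.character(records[[stratum_field]])),
                    reference_stratum)
  ref_rec <- records[records[[stratum_field]] == reference_stratum, ,
                     drop = FALSE]
  if (nrow(ref_rec) == 0) {
    stop("stratified_or: reference stratum has no records: ",
         reference_stratum)
  }
  rows <- list()
  for (s in sort(strata)) {
    sub <- records[records[[stratum_field]] == s, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning("stratified_or: skipping empty stratum: ", s)
      next
    }
    expo <- function(df, lev) sum(as.character(df[[exposure_field]]) == lev)
    tab <- contingency_2x2(expo(sub, exposed_level),
                           expo(ref_rec, exposed_level),
                           expo(sub, reference_level),
                           expo(ref_rec, reference_level))
    res <- woolf_or(tab)
    rows[[length(rows) + 1]] <- data.frame(
      stratum = s,
      exposed_stratum = tab$exposed_cases,
      exposed_reference = tab$exposed_controls,
      unexposed_stratum = tab$unexposed_cases,
      unexposed_reference = tab$unexposed_controls,
      odds_ratio = round(res$odds_ratio, 2),
      ci_low = round(res$ci_low, 2), ci_high = round(res$ci_high, 2),
      or_full = res$odds_ratio, ci_low_full = res$ci_low,
      ci_high_full = res$ci_high, corrected = res$corrected,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
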
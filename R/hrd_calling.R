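# BRCA1/2 variant-status filtering, the combined HRD call, concordance
# statistics and cohort summaries.

DELETERIOUS <- c("deleterious", "suspected_deleterious")

#' Filter annotated variants and derive BRCA1/2 mutation status
#'
#' Applies the assay's exclusion filters to pre-annotated variant records
#' and calls the sample's BRCA status. By default the two exclusions act
#' independently (a variant is dropped if its VAF is below `min_vaf` OR its
#' population frequency exceeds `max_pop_freq`); the conjunctive reading
#' (dropped only when both hold) is available via `exclusion = "both"`.
#' Records with missing VAF or population frequency are excluded with
#' reason `unannotated` and a warning. A sample is positive when at least
#' one retained BRCA1/2 variant is classified deleterious or suspected
#' deleterious.
#'
#' @param records Data frame with columns `gene`, `vaf`, `pop_freq`,
#'   `classification`, and optionally `variant_id`.
#' @param min_vaf VAF exclusion threshold (strict `<`, default 0.05).
#' @param max_pop_freq Population-frequency exclusion threshold
#'   (strict `>`, default 0.001).
#' @param exclusion `"either"` (default) or `"both"`.
#' @return Object of class `brca_status` with `status`,
#'   `supporting_variants`, `excluded` (with a `reason` column).
#' @export
filter_variants <- function(records, min_vaf = 0.05, max_pop_freq = 0.001,
                            exclusion = c("either", "both")) {
  exclusion <- match.arg(exclusion)
  if (is.null(records) || nrow(records) == 0L) {
    return(structure(list(status = "negative",
                          supporting_variants = empty_variants(),
                          excluded = cbind(empty_variants(),
                                           reason = character(0))),
                     class = "brca_status"))
  }
  need <- c("gene", "vaf", "pop_freq", "classification")
  if (!all(need %in% names(records)))
    stop2("variant records need columns: ", paste(need, collapse = ", "))
  if (!"variant_id" %in% names(records))
    records$variant_id <- paste0("v", seq_len(nrow(records)))
  unannotated <- is.na(records$vaf) | is.na(records$pop_freq)
  if (any(unannotated))
    warning(sum(unannotated), " variant(s) lack VAF or population frequency; excluded")
  low_vaf <- !unannotated & records$vaf < min_vaf
  common <- !unannotated & records$pop_freq > max_pop_freq
  excluded <- if (exclusion == "either") unannotated | low_vaf | common
              else unannotated | (low_vaf & common)
  reason <- character(nrow(records))
  reason[low_vaf] <- "low_vaf"
  reason[common] <- "common"
  reason[low_vaf & common] <- "low_vaf+common"
  reason[unannotated] <- "unannotated"
  supporting <- !excluded & records$gene %in% c("BRCA1", "BRCA2") &
    records$classification %in% DELETERIOUS
  structure(list(status = if (any(supporting)) "positive" else "negative",
                 supporting_variants = records[supporting, , drop = FALSE],
                 excluded = cbind(records[excluded, , drop = FALSE],
                                  reason = reason[excluded])),
            class = "brca_status")
}

empty_variants <- function() {
  data.frame(gene = character(0), vaf = numeric(0), pop_freq = numeric(0),
             classification = character(0), variant_id = character(0),
             stringsAsFactors = FALSE)
}

#' Combine QC, BRCA status, wGI status and TF into the HRD call
#'
#' Truth table of the assay: if any required QC gate failed, the sample is
#' `no_call`; otherwise the sample is HRD-positive when either the BRCA1/2
#' mutation status or the wGI status is positive, and negative when both
#' are negative. A tumour fraction below `tf_floor` (30%) appends a
#' reliability warning without changing the call.
#'
#' @param qc_targeted,qc_swgs [qc_result] objects for the two assays.
#' @param brca A [filter_variants()] result.
#' @param wgi A [wgi_score()] result, or `NULL` only if sWGS QC failed.
#' @param tf Optional [estimate_tf()] result (or bare fraction).
#' @param sample_id Sample identifier.
#' @param tf_floor Validated tumour-fraction floor.
#' @param extra_warnings Character vector of warnings to carry through.
#' @return Object of class `hrd_report`.
#' @export
combine_hrd <- function(qc_targeted, qc_swgs, brca, wgi, tf = NULL,
                        sample_id = "sample", tf_floor = 0.30,
                        extra_warnings = character(0)) {
  stopifnot(inherits(qc_targeted, "qc_result"), inherits(qc_swgs, "qc_result"))
  qc_ok <- qc_targeted$passed && qc_swgs$passed
  if (qc_swgs$passed && is.null(wgi))
    stop2("inconsistent state: sWGS QC passed but no wGI result supplied")
  warnings <- extra_warnings
  tf_fraction <- if (inherits(tf, "tf_estimate")) tf$fraction else tf
  if (!is.null(tf_fraction) && !is.na(tf_fraction) && tf_fraction < tf_floor)
    warnings <- c(warnings, sprintf(
      "tumour fraction %.2f below validated TF floor %.2f; result may be unreliable",
      tf_fraction, tf_floor))
  status <- if (!qc_ok) "no_call"
  else if (brca$status == "positive" || wgi$status == "positive") "positive"
  else "negative"
  structure(list(sample_id = sample_id,
                 qc = list(targeted = qc_targeted, swgs = qc_swgs),
                 brca = brca, wgi = wgi, tf = tf,
                 hrd_status = status, warnings = warnings),
            class = "hrd_report")
}

#' @export
print.hrd_report <- function(x, ...) {
  cat("hrd_report '", x$sample_id, "': ", x$hrd_status, sep = "")
  if (x$hrd_status != "no_call")
    cat(" (BRCA ", x$brca$status, ", wGI ", x$wgi$status, ")", sep = "")
  cat("\n")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Diagnostic concordance between two assays
#'
#' Tallies paired calls into a 2x2 table (second element is the reference)
#' and reports positive, negative and overall percent agreement. Pairs in
#' which either call is `no_call` are dropped and counted in `n_dropped`.
#' Percentages are rounded to one decimal, half away from zero; an
#' agreement whose denominator is zero is reported as `NA` (absent), never
#' as 0.
#'
#' @param test,reference Character vectors of calls
#'   (`positive`/`negative`/`no_call`), or `test` may be a two-column data
#'   frame of (test, reference) pairs.
#' @param positive_label The label counted as positive.
#' @return Object of class `concordance_result` with `tp`, `fp`, `fn`,
#'   `tn`, `n_used`, `n_dropped`, `ppa`, `npa`, `opa`.
#' @export
concordance <- function(test, reference = NULL, positive_label = "positive") {
  if (is.data.frame(test)) {
    reference <- test[[2]]
    test <- test[[1]]
  }
  if (length(test) == 0L) stop2("empty pair list")
  if (length(test) != length(reference))
    stop2("test and reference must have equal length")
  keep <- test != "no_call" & reference != "no_call" &
    !is.na(test) & !is.na(reference)
  n_dropped <- sum(!keep)
  test <- test[keep]; reference <- reference[keep]
  if (length(test) == 0L) stop2("no usable pairs after dropping no_calls")
  tp <- sum(test == positive_label & reference == positive_label)
  fp <- sum(test == positive_label & reference != positive_label)
  fn <- sum(test != positive_label & reference == positive_label)
  tn <- sum(test != positive_label & reference != positive_label)
  pct <- function(num, den) if (den == 0) NA_real_ else round_half_up(100 * num / den, 1)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 n_used = tp + fp + fn + tn, n_dropped = n_dropped,
                 ppa = pct(tp, tp + fn), npa = pct(tn, tn + fp),
                 opa = pct(tp + tn, tp + fp + fn + tn)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance (n=%d, dropped %d): PPA %s, NPA %s, OPA %s\n",
              x$n_used, x$n_dropped,
              ifelse(is.na(x$ppa), "NA", sprintf("%.1f%%", x$ppa)),
              ifelse(is.na(x$npa), "NA", sprintf("%.1f%%", x$npa)),
              ifelse(is.na(x$opa), "NA", sprintf("%.1f%%", x$opa))))
  invisible(x)
}

#' Cohort-level HRD summary
#'
#' Summarises a list of per-sample HRD reports: assay success rate
#' (QC-passing / total) and, among QC-passing samples, the prevalence of
#' HRD, BRCA positivity and wGI positivity, the fraction of HRD-positives
#' carrying both markers, and wGI positivity within the BRCA-wild-type and
#' BRCA-mutated strata. Percentages are to one decimal (half up); strata
#' with a zero denominator are `NA`.
#'
#' @param reports List of [combine_hrd()] reports.
#' @return A one-row data frame of counts and percentages.
#' @export
cohort_summary <- function(reports) {
  if (length(reports) == 0L) stop2("at least one report required")
  stopifnot(all(vapply(reports, inherits, logical(1), "hrd_report")))
  status <- vapply(reports, function(r) r$hrd_status, character(1))
  passing <- status != "no_call"
  n <- length(reports); n_pass <- sum(passing)
  pr <- reports[passing]
  brca_pos <- vapply(pr, function(r) r$brca$status == "positive", logical(1))
  wgi_pos <- vapply(pr, function(r) r$wgi$status == "positive", logical(1))
  hrd_pos <- vapply(pr, function(r) r$hrd_status == "positive", logical(1))
  pct <- function(num, den) if (den == 0) NA_real_ else round_half_up(100 * num / den, 1)
  data.frame(
    n_total = n, n_passing = n_pass,
    success_rate = pct(n_pass, n),
    n_hrd_positive = sum(hrd_pos),
    hrd_positive_pct = pct(sum(hrd_pos), n_pass),
    brca_positive_pct = pct(sum(brca_pos), n_pass),
    wgi_positive_pct = pct(sum(wgi_pos), n_pass),
    both_among_hrd_pct = pct(sum(brca_pos & wgi_pos), sum(hrd_pos)),
    wgi_pos_in_brca_wt_pct = pct(sum(wgi_pos & !brca_pos), sum(!brca_pos)),
    wgi_pos_in_brca_mut_pct = pct(sum(wgi_pos & brca_pos), sum(brca_pos)))
}
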
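# End-to-end drivers tying the stages into the published workflow.

#' Run the wGI pipeline on one sample
#'
#' Executes normalise -> segment -> noise index -> minimal CNA cutoff ->
#' merge -> LGA call -> wGI score -> tumour-fraction estimate on a raw bin
#' profile (or an indexed BAM, which is first counted into bins).
#'
#' The cutoff needs a tumour fraction before merging, so the pipeline is
#' two-pass: a provisional merge under a noise-only cutoff yields a
#' provisional TF, which sets the final cutoff; the reported TF is then
#' re-estimated on the final merged profile.
#'
#' If the sWGS QC gate fails, a fragment with `qc` filled in and the
#' analysis fields `NULL` is returned (downstream [run_hrd()] turns this
#' into a `no_call`).
#'
#' @param input A raw-stage [bin_profile()], or a path to an indexed BAM.
#' @param layout The `genome_layout` the bins belong to.
#' @param config A [wgi_config()].
#' @param swgs_stats Optional [depth_stats()] over the genome for the sWGS
#'   QC gate. When absent, a bin-level surrogate is derived from the bin
#'   counts and `config$read_length` (per-bin depth = count * read length /
#'   bin width; coverage fractions are then bin-level approximations).
#' @param bins Bin table (required when `input` is a BAM path); defaults to
#'   `make_bins(layout, config$bin_size)`.
#' @return Object of class `wgi_fragment`: `sample_id`, `qc_swgs`, `noise`,
#'   `tf`, `cutoff`, `segments` (merged), `lgas`, `wgi`, `warnings`,
#'   `config`.
#' @export
run_wgi <- function(input, layout, config = wgi_config(), swgs_stats = NULL,
                    bins = NULL) {
  stopifnot(inherits(layout, "genome_layout"), inherits(config, "wgi_config"))
  if (is.character(input)) {
    if (is.null(bins)) bins <- make_bins(layout, config$bin_size)
    input <- count_reads(input, bins, min_mapq = config$min_mapq)
  }
  stopifnot(inherits(input, "bin_profile"))
  if (input$stage != "raw") stop2("run_wgi expects a raw-stage profile")
  if (is.null(swgs_stats)) {
    width <- input$bins$end - input$bins$start
    depth <- input$raw_count * config$read_length / width
    swgs_stats <- depth_stats(depth, region_label = "genome (bin-level surrogate)",
                              thresholds = c(config$swgs_min_depth,
                                             config$targeted_min_depth))
  }
  qc <- qc_swgs(swgs_stats, min_depth = config$swgs_min_depth,
                min_cov = config$swgs_min_cov)
  fragment <- list(sample_id = input$sample_id, qc_swgs = qc, noise = NULL,
                   tf = NULL, cutoff = NULL, single_copy_flag = NA,
                   segments = NULL, lgas = NULL, wgi = NULL,
                   warnings = character(0), config = config)
  class(fragment) <- "wgi_fragment"
  if (!qc$passed) {
    fragment$warnings <- paste("sWGS QC failed:", paste(qc$reasons, collapse = "; "))
    return(fragment)
  }
  norm <- normalize_profile(input, map_min = config$map_min,
                            min_usable = config$min_usable_bins)
  seg1 <- segment_bins(norm, lambda = config$lambda,
                       min_seg_bins = config$min_seg_bins,
                       min_arm_bins = config$min_arm_bins)
  noise <- noise_index(norm, seg1, warn_threshold = config$noise_warn)
  t_grid <- seq(config$t_min, config$t_max, by = config$t_step)
  psi_grid <- seq(config$psi_min, config$psi_max, by = config$psi_step)
  prov_cutoff <- max(config$k_noise * noise$noise_index, 0.1)
  prov <- merge_segments(seg1, prov_cutoff, small_len = config$small_len)
  tf0 <- tryCatch(estimate_tf(prov, t_grid = t_grid, psi_grid = psi_grid),
                  error = function(e) NULL)
  tf_for_cutoff <- if (!is.null(tf0)) tf0$fraction else config$tf_floor
  cutoff <- cna_cutoff(noise, tf_for_cutoff,
                       k_noise = config$k_noise, k_tf = config$k_tf)
  merged <- merge_segments(seg1, cutoff, small_len = config$small_len)
  lgas <- call_lgas(merged, min_len = config$min_len,
                    max_gap = config$max_gap, cutoff = cutoff)
  wgi <- wgi_score(nrow(lgas), baseline = config$baseline,
                   comparator = config$comparator)
  tf <- tryCatch(estimate_tf(merged, t_grid = t_grid, psi_grid = psi_grid),
                 error = function(e) tf0)
  warnings <- character(0)
  if (noise$warning)
    warnings <- c(warnings, sprintf("noise index %.3f above %.2f warning level",
                                    noise$noise_index, config$noise_warn))
  if (isTRUE(attr(cutoff, "single_copy_flag")))
    warnings <- c(warnings, "CNA cutoff at or above the single-copy signal; single-copy events may be unresolvable")
  fragment$noise <- noise
  fragment$tf <- tf
  fragment$cutoff <- as.numeric(cutoff)
  fragment$single_copy_flag <- isTRUE(attr(cutoff, "single_copy_flag"))
  fragment$segments <- merged
  fragment$lgas <- lgas
  fragment$wgi <- wgi
  fragment$warnings <- warnings
  fragment
}

#' @export
print.wgi_fragment <- function(x, ...) {
  cat("wgi_fragment '", x$sample_id, "': ", sep = "")
  if (is.null(x$wgi)) {
    cat("sWGS QC failed\n")
  } else {
    cat(sprintf("%d LGAs, score %+d (%s), TF %.2f, noise %.3f, cutoff %.3f\n",
                x$wgi$lga_count, x$wgi$score, x$wgi$status, x$tf$fraction,
                x$noise$noise_index, x$cutoff))
  }
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Combine a wGI fragment with BRCA variant status into the final HRD call
#'
#' Applies [filter_variants()] to the sample's annotated variants and
#' [combine_hrd()] to the QC pair, BRCA status and wGI result.
#'
#' @param fragment A [run_wgi()] result.
#' @param variants Annotated variant data frame (see [filter_variants()]),
#'   or `NULL` for none.
#' @param targeted_stats A [depth_stats()] over the BRCA1/2 region, an
#'   existing `qc_result`, or `NULL` to record the targeted gate as passed
#'   (variants supplied externally are assumed QC'ed upstream).
#' @param config A [wgi_config()] (defaults to the fragment's).
#' @return An `hrd_report`.
#' @export
run_hrd <- function(fragment, variants = NULL, targeted_stats = NULL,
                    config = NULL) {
  stopifnot(inherits(fragment, "wgi_fragment"))
  config <- config %||% fragment$config
  qc_t <- if (inherits(targeted_stats, "qc_result")) targeted_stats
  else if (inherits(targeted_stats, "depth_stats"))
    qc_targeted(targeted_stats, min_depth = config$targeted_min_depth,
                min_cov = config$targeted_min_cov)
  else qc_result(TRUE, "targeted", character(0))
  brca <- filter_variants(variants, min_vaf = config$min_vaf,
                          max_pop_freq = config$max_pop_freq,
                          exclusion = config$exclusion)
  combine_hrd(qc_t, fragment$qc_swgs, brca, fragment$wgi, fragment$tf,
              sample_id = fragment$sample_id, tf_floor = config$tf_floor,
              extra_warnings = fragment$warnings)
}
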
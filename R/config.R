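# Pipeline configuration: one place for every tunable, echoed into outputs.

#' Pipeline configuration
#'
#' Collects every tunable of the wGI/HRD pipeline with its default. The
#' full configuration is echoed into every JSON report header so results
#' are reproducible from the output alone.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return Object of class `wgi_config` (a named list).
#' @details Defaults: `bin_size` 500 kb; `min_mapq` 20; `map_min` 0.75;
#'   `min_usable_bins` 50; segmentation `lambda` 10, `min_seg_bins` 3,
#'   `min_arm_bins` 6; cutoff multipliers `k_noise` 2.5, `k_tf` 0.5;
#'   `small_len` 3 Mb; LGA `min_len` 10 Mb, `max_gap` 3 Mb; wGI `baseline`
#'   20 with comparator `ge_zero`; TF grid 0.05..1.00 by 0.01 over ploidy
#'   1.6..4.0 by 0.1; `tf_floor` 0.30; `noise_warn` 0.10; QC gates 40X/90%
#'   (targeted) and 1X/40% (sWGS); `read_length` 100 (for the bin-level
#'   depth surrogate); variant filters `min_vaf` 0.05, `max_pop_freq`
#'   0.001, `exclusion` "either".
#' @export
wgi_config <- function(...) {
  cfg <- list(
    bin_size = 5e5,
    min_mapq = 20,
    map_min = 0.75,
    min_usable_bins = 50,
    lambda = 10,
    min_seg_bins = 3L,
    min_arm_bins = 6L,
    k_noise = 2.5,
    k_tf = 0.5,
    small_len = 3e6,
    min_len = 1e7,
    max_gap = 3e6,
    baseline = 20L,
    comparator = "ge_zero",
    t_min = 0.05, t_max = 1.00, t_step = 0.01,
    psi_min = 1.6, psi_max = 4.0, psi_step = 0.1,
    tf_floor = 0.30,
    noise_warn = 0.10,
    targeted_min_depth = 40, targeted_min_cov = 0.90,
    swgs_min_depth = 1, swgs_min_cov = 0.40,
    read_length = 100,
    min_vaf = 0.05, max_pop_freq = 0.001, exclusion = "either")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L)
    stop2("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "wgi_config")
}

#' @export
print.wgi_config <- function(x, ...) {
  cat("wgi_config:\n")
  for (nm in names(x)) cat(" ", nm, "=", format(x[[nm]]), "\n")
  invisible(x)
}
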
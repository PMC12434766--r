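# Large-scale genomic alteration (LGA) calling and the wGI score.

#' Call large-scale genomic alterations
#'
#' An LGA is an intra-arm break between two adjacent genomic segments that
#' are each longer than `min_len` (strictly more than 10 Mb), separated by a
#' gap of strictly less than `max_gap` (3 Mb), with a mean log2-ratio
#' difference at or above the minimal CNA cutoff. Segment pairs never span
#' the centromere because segments are arm-confined by construction.
#'
#' @param sp A merged [segment_profile()].
#' @param min_len Minimum flanking-segment length in bp (strict `>`).
#' @param max_gap Maximum gap between the segments in bp (strict `<`).
#' @param cutoff Minimal |mean difference| for an event; defaults to the
#'   cutoff recorded at merge time.
#' @return Data frame of calls: `chromosome`, `arm`, `break_position`,
#'   `left_start`, `left_end`, `left_mean`, `right_start`, `right_end`,
#'   `right_mean`, `gap`, `delta`.
#' @export
call_lgas <- function(sp, min_len = 1e7, max_gap = 3e6, cutoff = NULL) {
  stopifnot(inherits(sp, "segment_profile"))
  if (!isTRUE(sp$merged)) stop2("merge before calling: run merge_segments() first")
  cutoff <- cutoff %||% sp$cna_cutoff_used
  if (is.na(cutoff)) stop2("no cutoff available; supply one")
  cutoff <- as.numeric(cutoff)
  seg <- sp$segments
  out <- list()
  for (key in unique(paste(seg$chromosome, seg$arm))) {
    s <- seg[paste(seg$chromosome, seg$arm) == key, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) < 2L) next
    for (i in seq_len(nrow(s) - 1L)) {
      a <- s[i, ]; b <- s[i + 1L, ]
      gap <- b$start - a$end
      delta <- abs(a$mean_ratio - b$mean_ratio)
      if (a$length > min_len && b$length > min_len &&
          gap < max_gap && delta >= cutoff) {
        out[[length(out) + 1L]] <- data.frame(
          chromosome = a$chromosome, arm = a$arm,
          break_position = floor((a$end + b$start) / 2),
          left_start = a$start, left_end = a$end, left_mean = a$mean_ratio,
          right_start = b$start, right_end = b$end, right_mean = b$mean_ratio,
          gap = gap, delta = delta, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chromosome = character(0), arm = character(0),
                      break_position = numeric(0), left_start = numeric(0),
                      left_end = numeric(0), left_mean = numeric(0),
                      right_start = numeric(0), right_end = numeric(0),
                      right_mean = numeric(0), gap = numeric(0),
                      delta = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Whole-genome instability (wGI) score
#'
#' Shifts the LGA count by a scaling baseline so that 0 is the positivity
#' cutoff: `score = lga_count - baseline`. With the default comparator a
#' score of exactly 0 is positive (borderline-positive convention); the
#' strict comparator `"gt_zero"` is available.
#'
#' @param lga_count Non-negative integer number of LGA events.
#' @param baseline Scaling baseline L0 (default 20).
#' @param comparator `"ge_zero"` (default) or `"gt_zero"`.
#' @return Object of class `wgi_result` with `lga_count`, `baseline`,
#'   `score`, `status`, `comparator`.
#' @export
wgi_score <- function(lga_count, baseline = 20, comparator = c("ge_zero", "gt_zero")) {
  comparator <- match.arg(comparator)
  if (!is.numeric(lga_count) || lga_count < 0 || lga_count != floor(lga_count))
    stop2("lga_count must be a non-negative integer")
  if (!is.numeric(baseline) || baseline < 0)
    stop2("baseline must be non-negative")
  score <- as.integer(lga_count - baseline)
  positive <- if (comparator == "ge_zero") score >= 0 else score > 0
  structure(list(lga_count = as.integer(lga_count),
                 baseline = as.integer(baseline), score = score,
                 status = if (positive) "positive" else "negative",
                 comparator = comparator),
            class = "wgi_result")
}

#' @export
print.wgi_result <- function(x, ...) {
  cat(sprintf("wGI: %d LGAs, score %+d (baseline %d) -> %s\n",
              x$lga_count, x$score, x$baseline, x$status))
  invisible(x)
}
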
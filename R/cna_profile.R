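# GC normalisation of bin counts and the within-segment noise index.

#' Normalise bin counts and compute centred log2 copy ratios
#'
#' QDNAseq-style correction re-expressed deterministically: usable bins are
#' grouped into GC deciles and each count is rescaled by the ratio of the
#' genome-wide median count to its decile's median, then log2 ratios are
#' centred on the median corrected count. Bins with mappability below
#' `map_min`, missing GC, or zero raw count carry no ratio and are marked
#' unusable; a GC decile whose median corrected count is zero has all its
#' bins marked unusable (with a warning).
#'
#' @param profile Raw-stage [bin_profile()]. GC (and optionally mappability)
#'   are taken from `profile$bins` unless supplied here.
#' @param gc,mappability Optional per-bin tracks overriding `profile$bins`.
#' @param map_min Mappability floor below which a bin is unusable.
#' @param n_gc_bins Number of GC groups (deciles by default).
#' @param min_usable Minimum usable bins required; fewer is an error.
#' @return A normalized-stage `bin_profile` with `corrected` and
#'   `log2_ratio` filled in and `bins$usable` updated.
#' @export
normalize_profile <- function(profile, gc = NULL, mappability = NULL,
                              map_min = 0.75, n_gc_bins = 10,
                              min_usable = 50) {
  stopifnot(inherits(profile, "bin_profile"))
  bins <- profile$bins
  if (!is.null(gc)) bins$gc <- gc
  if (!is.null(mappability)) bins$mappability <- mappability
  raw <- profile$raw_count
  usable <- bins$usable & !is.na(bins$gc) & raw > 0 &
    (is.na(bins$mappability) | bins$mappability >= map_min)
  if (sum(usable) < min_usable) stop2("profile too sparse: ",
                                      sum(usable), " usable bins")
  gc_u <- bins$gc[usable]
  br <- unique(stats::quantile(gc_u, probs = seq(0, 1, length.out = n_gc_bins + 1)))
  if (length(br) < 2L) {
    grp <- factor(rep(1L, sum(usable)))
  } else {
    grp <- cut(gc_u, breaks = br, include.lowest = TRUE)
  }
  gmed <- stats::median(raw[usable])
  dec_med <- tapply(raw[usable], grp, stats::median)
  corrected <- rep(NA_real_, length(raw))
  fac <- gmed / dec_med[as.character(grp)]
  corrected[usable] <- raw[usable] * as.numeric(fac)
  zero_grp <- names(dec_med)[dec_med == 0]
  if (length(zero_grp) > 0L) {
    warning("GC group(s) with zero median count; their bins marked unusable")
    bad <- which(usable)[as.character(grp) %in% zero_grp]
    usable[bad] <- FALSE
    corrected[bad] <- NA_real_
  }
  m <- stats::median(corrected[usable])
  log2_ratio <- rep(NA_real_, length(raw))
  log2_ratio[usable] <- log2(corrected[usable] / m)
  bins$usable <- usable
  bin_profile(bins, raw, sample_id = profile$sample_id,
              corrected = corrected, log2_ratio = log2_ratio,
              stage = "normalized")
}

#' Within-segment noise index
#'
#' Measures the median fluctuation of bins within each copy-number segment:
#' for every segment the median absolute deviation (MAD, without consistency
#' scaling) of its bins' log2 ratios about the segment median is computed,
#' and the noise index is the median of those per-segment MADs; their
#' standard deviation is retained alongside. Being a within-segment
#' statistic, it is invariant to level shifts of whole segments and so
#' reflects technical noise (FFPE degradation) rather than biology. Values
#' above `warn_threshold` (0.10) flag a sample as at risk of failure, not a
#' hard failure.
#'
#' @param profile Normalized-stage [bin_profile()].
#' @param segments A [segment_profile()] assigning bins to segments.
#' @param aggregate `"segment"` (median of per-segment MADs, default) or
#'   `"bin"` (a single MAD over all within-segment deviations pooled).
#' @param warn_threshold Warning level for the noise index.
#' @return Object of class `noise_stats` with `per_segment_mad`,
#'   `noise_index`, `noise_sd`, `n_usable_bins`, `warning`.
#' @export
noise_index <- function(profile, segments, aggregate = c("segment", "bin"),
                        warn_threshold = 0.10) {
  stopifnot(inherits(profile, "bin_profile"),
            inherits(segments, "segment_profile"))
  if (profile$stage != "normalized") stop2("profile must be normalized first")
  aggregate <- match.arg(aggregate)
  seg <- segments$segments
  bins <- profile$bins
  r <- profile$log2_ratio
  mads <- numeric(0)
  pooled <- numeric(0)
  n_used <- 0L
  for (i in seq_len(nrow(seg))) {
    in_seg <- bins$usable & bins$chromosome == seg$chromosome[i] &
      bins$arm == seg$arm[i] & bins$start >= seg$start[i] &
      bins$start < seg$end[i]
    ri <- r[in_seg]
    if (length(ri) < 2L) next
    dev <- abs(ri - stats::median(ri))
    mads <- c(mads, stats::median(dev))
    pooled <- c(pooled, dev)
    n_used <- n_used + length(ri)
  }
  if (length(mads) == 0L)
    stop2("no segment with at least 2 usable bins; cannot estimate noise")
  ni <- if (aggregate == "segment") stats::median(mads) else stats::median(pooled)
  structure(list(per_segment_mad = mads,
                 noise_index = ni,
                 noise_sd = if (length(mads) > 1L) stats::sd(mads) else 0,
                 n_usable_bins = n_used,
                 warning = ni > warn_threshold),
            class = "noise_stats")
}

#' @export
print.noise_stats <- function(x, ...) {
  cat(sprintf("noise_stats: index %.4f (sd %.4f) over %d segments%s\n",
              x$noise_index, x$noise_sd, length(x$per_segment_mad),
              if (x$warning) " [WARNING: above 0.10]" else ""))
  invisible(x)
}
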
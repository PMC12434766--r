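# Read counting into bins and the sequencing QC gates.

#' Construct a bin profile
#'
#' Container for per-bin read counts and, after normalisation, corrected
#' counts and centred log2 copy ratios.
#'
#' @param bins Bin data frame from [make_bins()].
#' @param raw_count Non-negative integer vector, one per bin.
#' @param sample_id Sample identifier.
#' @param corrected Optional numeric vector of GC-corrected counts.
#' @param log2_ratio Optional numeric vector of centred log2 ratios.
#' @param stage One of `"raw"`, `"corrected"`, `"normalized"`.
#' @return Object of class `bin_profile`.
#' @export
bin_profile <- function(bins, raw_count, sample_id = "sample",
                        corrected = NULL, log2_ratio = NULL, stage = "raw") {
  stopifnot(is.data.frame(bins), length(raw_count) == nrow(bins))
  if (any(is.na(raw_count)) || any(raw_count < 0) ||
      any(raw_count != floor(raw_count)))
    stop2("raw_count must be non-negative integers")
  stage <- match.arg(stage, c("raw", "corrected", "normalized"))
  if (stage == "normalized" && is.null(log2_ratio))
    stop2("normalized stage requires log2_ratio")
  if (!is.null(corrected)) stopifnot(length(corrected) == nrow(bins))
  if (!is.null(log2_ratio)) stopifnot(length(log2_ratio) == nrow(bins))
  structure(list(bins = bins, raw_count = as.numeric(raw_count),
                 corrected = corrected, log2_ratio = log2_ratio,
                 sample_id = sample_id, stage = stage),
            class = "bin_profile")
}

#' @export
print.bin_profile <- function(x, ...) {
  cat("bin_profile '", x$sample_id, "': ", nrow(x$bins), " bins (",
      sum(x$bins$usable), " usable), stage ", x$stage, "\n", sep = "")
  invisible(x)
}

#' Count filtered reads into bins
#'
#' Counts alignments from a coordinate-sorted, indexed BAM file into bins.
#' Only primary, mapped, properly paired, non-duplicate alignments with
#' mapping quality at or above `min_mapq` are counted; each read is assigned
#' to exactly one bin by its leftmost aligned position. Reads falling outside
#' every bin (or on chromosomes absent from the bin set) are ignored but
#' tallied in the `n_ignored` attribute, so
#' `sum(raw_count) + attr(, "n_ignored")` equals the total number of
#' filter-passing reads in the file.
#'
#' @param bam_file Path to an indexed BAM.
#' @param bins Bin data frame from [make_bins()].
#' @param min_mapq Mapping-quality floor (default 20).
#' @param sample_id Sample identifier; defaults to the file name.
#' @return A raw-stage [bin_profile()] with attribute `n_ignored`.
#' @export
count_reads <- function(bam_file, bins, min_mapq = 20,
                        sample_id = sub("\\.bam$", "", basename(bam_file))) {
  if (!file.exists(bam_file)) stop2("BAM file not found: ", bam_file)
  idx <- paste0(bam_file, ".bai")
  idx2 <- sub("\\.bam$", ".bai", bam_file)
  if (!file.exists(idx) && !file.exists(idx2))
    stop2("BAM index (.bai) not found for ", bam_file,
          "; create one with samtools index or Rsamtools::indexBam()")
  header <- Rsamtools::scanBamHeader(bam_file)[[1]]$targets
  chroms <- unique(bins$chromosome)
  missing <- setdiff(chroms, names(header))
  if (length(missing) > 0L)
    stop2("chromosomes in bin set absent from BAM header: ",
          paste(missing, collapse = ", "))
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isProperPair = TRUE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE)
  which <- GenomicRanges::GRanges(chroms,
            IRanges::IRanges(1, unname(header[chroms])))
  param <- Rsamtools::ScanBamParam(flag = flags, what = "pos",
                                   mapqFilter = min_mapq, which = which)
  res <- Rsamtools::scanBam(bam_file, param = param)
  counts <- numeric(nrow(bins))
  n_on_chroms <- 0L
  for (k in seq_along(res)) {
    chr <- as.character(GenomicRanges::seqnames(which))[k]
    pos1 <- res[[k]]$pos          # 1-based leftmost
    if (length(pos1) == 0L) next
    n_on_chroms <- n_on_chroms + length(pos1)
    sel <- which(bins$chromosome == chr)
    b <- bins[sel, ]
    pos0 <- pos1 - 1
    i <- findInterval(pos0, b$start)
    ok <- i >= 1L & pos0 < b$end[pmax(i, 1L)]
    tab <- tabulate(i[ok], nbins = nrow(b))
    counts[sel] <- counts[sel] + tab
  }
  total_param <- Rsamtools::ScanBamParam(flag = flags, what = character(0),
                                         mapqFilter = min_mapq)
  total <- Rsamtools::countBam(bam_file, param = total_param)$records
  prof <- bin_profile(bins, counts, sample_id = sample_id, stage = "raw")
  attr(prof, "n_ignored") <- total - sum(counts)
  prof
}

#' Depth statistics over a region
#'
#' Summarises per-base sequencing depth: mean depth and the fraction of
#' positions covered at or above each requested threshold. These feed the
#' QC gates [qc_targeted()] and [qc_swgs()].
#'
#' @param depth Numeric vector of per-base depths over the region, or a data
#'   frame with a `depth` column.
#' @param region_label Free-text label.
#' @param thresholds Depth thresholds (X) at which to report coverage.
#' @return Object of class `depth_stats` with `mean_depth` and named
#'   `coverage_at` fractions.
#' @export
depth_stats <- function(depth, region_label = "region", thresholds = c(1, 40)) {
  if (is.data.frame(depth)) depth <- depth$depth
  if (!is.numeric(depth) || length(depth) == 0L)
    stop2("depth must be a non-empty numeric vector (empty region?)")
  if (any(is.na(depth)) || any(depth < 0)) stop2("depths must be non-negative")
  cov <- vapply(thresholds, function(t) mean(depth >= t), numeric(1))
  names(cov) <- as.character(thresholds)
  structure(list(region_label = region_label, mean_depth = mean(depth),
                 coverage_at = cov),
            class = "depth_stats")
}

#' Per-base depth from a BAM over a region
#'
#' Convenience pileup wrapper returning a per-base depth vector (zeros
#' included) suitable for [depth_stats()]. Coordinates are 0-based half-open.
#'
#' @param bam_file Indexed BAM path.
#' @param chromosome,start,end Region.
#' @return Numeric vector of length `end - start`.
#' @export
bam_depth <- function(bam_file, chromosome, start, end) {
  if (end <= start) stop2("empty region")
  which <- GenomicRanges::GRanges(chromosome, IRanges::IRanges(start + 1, end))
  sbp <- Rsamtools::ScanBamParam(which = which)
  pp <- Rsamtools::PileupParam(distinguish_strands = FALSE,
                               distinguish_nucleotides = FALSE,
                               min_base_quality = 0, min_mapq = 0,
                               min_nucleotide_depth = 1,
                               max_depth = 100000L)
  p <- Rsamtools::pileup(bam_file, scanBamParam = sbp, pileupParam = pp)
  depth <- numeric(end - start)
  if (nrow(p) > 0L) {
    agg <- stats::aggregate(count ~ pos, data = p, FUN = sum)
    depth[agg$pos - start] <- agg$count
  }
  depth
}

qc_result <- function(passed, rule, reasons, stats = NULL) {
  stopifnot(passed == (length(reasons) == 0L))
  structure(list(passed = passed, rule = rule, reasons = reasons,
                 mean_depth = stats$mean_depth %||% NA_real_,
                 coverage_at = stats$coverage_at %||% NULL),
            class = "qc_result")
}

get_cov <- function(stats, threshold) {
  key <- as.character(threshold)
  if (is.null(stats$coverage_at) || !key %in% names(stats$coverage_at))
    stop2("depth_stats lacks coverage_at(", key, "X); recompute with that threshold")
  unname(stats$coverage_at[[key]])
}

#' QC gate for deep targeted (BRCA1/2) sequencing
#'
#' A sample passes when the mean depth over the targeted region is strictly
#' greater than `min_depth` (40X) and the fraction of positions covered at
#' `min_depth` is at least `min_cov` (90%). Strict vs non-strict comparisons
#' follow the assay definition exactly.
#'
#' @param stats A [depth_stats()] over the targeted region, computed with a
#'   threshold at `min_depth`.
#' @param min_depth,min_cov Gate parameters.
#' @return Object of class `qc_result`.
#' @export
qc_targeted <- function(stats, min_depth = 40, min_cov = 0.90) {
  stopifnot(inherits(stats, "depth_stats"))
  cov <- get_cov(stats, min_depth)
  reasons <- character(0)
  if (!(stats$mean_depth > min_depth))
    reasons <- c(reasons, sprintf("mean depth %.2fX not > %gX", stats$mean_depth, min_depth))
  if (!(cov >= min_cov))
    reasons <- c(reasons, sprintf("coverage at %gX is %.1f%% < %.0f%%",
                                  min_depth, 100 * cov, 100 * min_cov))
  qc_result(length(reasons) == 0L, "targeted", reasons, stats)
}

#' QC gate for shallow WGS
#'
#' A sample passes when genome-wide mean depth is strictly greater than
#' `min_depth` (1X) and the fraction of positions covered at `min_depth` is
#' at least `min_cov` (40%).
#'
#' @inheritParams qc_targeted
#' @return Object of class `qc_result`.
#' @export
qc_swgs <- function(stats, min_depth = 1, min_cov = 0.40) {
  stopifnot(inherits(stats, "depth_stats"))
  cov <- get_cov(stats, min_depth)
  reasons <- character(0)
  if (!(stats$mean_depth > min_depth))
    reasons <- c(reasons, sprintf("mean depth %.2fX not > %gX", stats$mean_depth, min_depth))
  if (!(cov >= min_cov))
    reasons <- c(reasons, sprintf("coverage at %gX is %.1f%% < %.0f%%",
                                  min_depth, 100 * cov, 100 * min_cov))
  qc_result(length(reasons) == 0L, "swgs", reasons, stats)
}
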
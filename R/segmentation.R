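# Penalized optimal-partitioning segmentation of log2 ratios, the
# noise/TF-adaptive minimal CNA cutoff, and iterative segment merging.

#' Construct a segment profile
#'
#' @param segments Data frame with columns `chromosome`, `arm`, `start`,
#'   `end`, `n_bins`, `bin_bp` (total bp of member bins, the weight used for
#'   means), `mean_ratio`.
#' @param sample_id Sample identifier.
#' @param merged Whether iterative merging has been applied.
#' @param cna_cutoff_used The minimal CNA cutoff used for merging, if any.
#' @return Object of class `segment_profile`.
#' @export
segment_profile <- function(segments, sample_id = "sample", merged = FALSE,
                            cna_cutoff_used = NA_real_) {
  need <- c("chromosome", "arm", "start", "end", "n_bins", "bin_bp", "mean_ratio")
  stopifnot(is.data.frame(segments), all(need %in% names(segments)))
  stopifnot(all(segments$n_bins >= 1))
  for (key in unique(paste(segments$chromosome, segments$arm))) {
    s <- segments[paste(segments$chromosome, segments$arm) == key, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1L && any(s$end[-nrow(s)] > s$start[-1]))
      stop2("overlapping segments on ", key)
  }
  segments$length <- segments$end - segments$start
  rownames(segments) <- NULL
  structure(list(segments = segments, sample_id = sample_id, merged = merged,
                 cna_cutoff_used = cna_cutoff_used),
            class = "segment_profile")
}

#' @export
print.segment_profile <- function(x, ...) {
  cat("segment_profile '", x$sample_id, "': ", nrow(x$segments),
      " segments", if (x$merged) sprintf(", merged (cutoff %.3f)",
                                         x$cna_cutoff_used) else "", "\n",
      sep = "")
  invisible(x)
}

# Exact penalized optimal partitioning of one numeric sequence.
# Minimises total within-segment SSE + penalty per changepoint, with a
# minimum segment size. Returns integer segment ids (1-based, consecutive).
# Deterministic; ties resolve to fewer/earlier changepoints.
optimal_partition <- function(r, penalty, min_seg = 3L) {
  n <- length(r)
  if (n < 2L * min_seg) return(rep(1L, n))
  s1 <- c(0, cumsum(r))
  s2 <- c(0, cumsum(r^2))
  f <- rep(Inf, n + 1)
  f[1] <- -penalty
  back <- integer(n + 1)
  for (j in min_seg:n) {
    cand <- 0L
    if (j - min_seg >= min_seg)
      cand <- c(0L, seq.int(min_seg, j - min_seg))
    len <- j - cand
    sums <- s1[j + 1] - s1[cand + 1]
    v <- f[cand + 1] + penalty + (s2[j + 1] - s2[cand + 1]) - sums^2 / len
    ok <- is.finite(v)
    if (!any(ok)) next
    bi <- cand[ok][which(v[ok] <= min(v[ok]) + 1e-12)[1]]  # ties -> fewer/earlier cps
    f[j + 1] <- min(v[ok])
    back[j + 1] <- bi
  }
  # backtrace
  cps <- integer(0)
  j <- n
  while (j > 0) {
    i <- back[j + 1]
    cps <- c(i, cps)
    j <- i
  }
  bounds <- c(cps, n)                 # 0, cp..., n
  ids <- integer(n)
  for (k in seq_len(length(bounds) - 1))
    ids[(bounds[k] + 1):bounds[k + 1]] <- k
  ids
}

#' Segment a normalized bin profile
#'
#' Per chromosome arm, finds the exact minimiser of the penalized
#' least-squares cost (within-segment sum of squares plus
#' `lambda * sigma^2` per changepoint) over all partitions of the usable
#' bins, with a minimum segment size of `min_seg_bins`. The noise scale
#' `sigma` is estimated robustly from median absolute successive
#' differences, so level shifts between true segments do not inflate it.
#' Deterministic: no randomness, ties resolve to fewer changepoints.
#'
#' @param profile Normalized-stage [bin_profile()].
#' @param lambda Penalty multiplier (default 10): a changepoint is accepted
#'   only if it reduces the cost by more than `lambda * sigma^2`.
#' @param min_seg_bins Minimum bins per segment (default 3).
#' @param min_arm_bins Arms with fewer usable bins are returned as one
#'   flagged segment (attribute `flagged_arms`).
#' @return An unmerged [segment_profile()].
#' @export
segment_bins <- function(profile, lambda = 10, min_seg_bins = 3L,
                         min_arm_bins = 6L) {
  stopifnot(inherits(profile, "bin_profile"))
  if (profile$stage != "normalized") stop2("profile must be normalized first")
  bins <- profile$bins
  r_all <- profile$log2_ratio
  keys <- unique(bins[, c("chromosome", "arm")])
  segs <- list()
  flagged <- character(0)
  for (k in seq_len(nrow(keys))) {
    sel <- which(bins$usable & bins$chromosome == keys$chromosome[k] &
                 bins$arm == keys$arm[k])
    if (length(sel) == 0L) next
    sel <- sel[order(bins$start[sel])]
    r <- r_all[sel]
    n <- length(r)
    if (n < min_arm_bins) {
      ids <- rep(1L, n)
      flagged <- c(flagged, paste0(keys$chromosome[k], keys$arm[k]))
    } else {
      sigma <- stats::median(abs(diff(r))) / 0.9539
      penalty <- max(lambda * sigma^2, 1e-12)
      ids <- optimal_partition(r, penalty, min_seg = min_seg_bins)
    }
    w <- bins$end[sel] - bins$start[sel]
    for (id in unique(ids)) {
      m <- ids == id
      segs[[length(segs) + 1L]] <- data.frame(
        chromosome = keys$chromosome[k], arm = keys$arm[k],
        start = min(bins$start[sel[m]]), end = max(bins$end[sel[m]]),
        n_bins = sum(m), bin_bp = sum(w[m]),
        mean_ratio = sum(w[m] * r[m]) / sum(w[m]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(segs) == 0L) stop2("no usable bins to segment")
  sp <- segment_profile(do.call(rbind, segs), sample_id = profile$sample_id)
  attr(sp, "flagged_arms") <- flagged
  sp
}

#' Noise- and tumour-fraction-adaptive minimal CNA cutoff
#'
#' The smallest |log2-ratio difference| treated as a real copy-number event.
#' Two considerations set it: FFPE noise (the cutoff must clear random
#' within-segment fluctuation, term `k_noise * noise_index`) and tumour
#' fraction (a single-copy gain at tumour fraction `t` only moves the ratio
#' by about `log2(1 + t/2)`, term `k_tf * log2(1 + t/2)`); the cutoff is the
#' larger of the two. When the cutoff reaches or exceeds the full
#' single-copy signal `log2(1 + t/2)`, single-copy events may be
#' unresolvable and the result carries attribute `single_copy_flag = TRUE`.
#'
#' @param noise A [noise_index()] result or a bare noise-index number.
#' @param tf A [estimate_tf()] result or a bare tumour fraction in (0, 1].
#' @param k_noise,k_tf Multipliers (defaults 2.5 and 0.5).
#' @return Positive numeric cutoff with attribute `single_copy_flag`.
#' @export
cna_cutoff <- function(noise, tf, k_noise = 2.5, k_tf = 0.5) {
  ni <- if (inherits(noise, "noise_stats")) noise$noise_index else noise
  t <- if (inherits(tf, "tf_estimate")) tf$fraction else tf
  stopifnot(is.numeric(ni), ni >= 0)
  if (!is.numeric(t) || t <= 0 || t > 1)
    stop2("tumour fraction must be in (0, 1]")
  single_copy <- log2(1 + t / 2)
  cutoff <- max(k_noise * ni, k_tf * single_copy)
  attr(cutoff, "single_copy_flag") <- cutoff >= single_copy
  cutoff
}

# Merge rows i and i+1 of a per-arm segment data frame.
merge_pair <- function(s, i) {
  w <- s$bin_bp[i] + s$bin_bp[i + 1]
  s$mean_ratio[i] <- (s$bin_bp[i] * s$mean_ratio[i] +
                      s$bin_bp[i + 1] * s$mean_ratio[i + 1]) / w
  s$end[i] <- s$end[i + 1]
  s$n_bins[i] <- s$n_bins[i] + s$n_bins[i + 1]
  s$bin_bp[i] <- w
  s$length[i] <- s$end[i] - s$start[i]
  s[-(i + 1), , drop = FALSE]
}

#' Iteratively merge segments below the minimal CNA cutoff
#'
#' Within each arm, iterates to a fixpoint: (1) every segment shorter than
#' `small_len` (3 Mb) is absorbed into the adjacent segment with the closer
#' mean ratio (ties to the left), shortest segment first; (2) among adjacent
#' pairs whose |mean difference| is below `cutoff`, the pair with the
#' smallest difference is merged first, means recomputed (bin-bp weighted),
#' and the scan repeated. After merging, every surviving adjacent boundary
#' within an arm is a copy-number event at the cutoff scale.
#'
#' @param sp An unmerged [segment_profile()].
#' @param cutoff Minimal CNA cutoff from [cna_cutoff()].
#' @param small_len Segments shorter than this are absorbed (default 3 Mb,
#'   matching the LGA gap-bridging scale).
#' @return A merged `segment_profile` with `cna_cutoff_used` recorded.
#' @export
merge_segments <- function(sp, cutoff, small_len = 3e6) {
  stopifnot(inherits(sp, "segment_profile"))
  cutoff <- as.numeric(cutoff)
  if (!is.finite(cutoff) || cutoff <= 0) stop2("cutoff must be positive")
  seg <- sp$segments
  out <- list()
  for (key in unique(paste(seg$chromosome, seg$arm))) {
    s <- seg[paste(seg$chromosome, seg$arm) == key, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    repeat {
      n_before <- nrow(s)
      # (1) absorb small segments, shortest first
      repeat {
        small <- which(s$length < small_len)
        if (length(small) == 0L || nrow(s) == 1L) break
        i <- small[which.min(s$length[small])]
        if (i == 1L) nb <- 2L
        else if (i == nrow(s)) nb <- nrow(s) - 1L
        else {
          dl <- abs(s$mean_ratio[i] - s$mean_ratio[i - 1])
          dr <- abs(s$mean_ratio[i] - s$mean_ratio[i + 1])
          nb <- if (dl <= dr) i - 1L else i + 1L
        }
        s <- merge_pair(s, min(i, nb))
      }
      # (2) merge closest sub-cutoff adjacent pair, repeatedly
      repeat {
        if (nrow(s) == 1L) break
        d <- abs(diff(s$mean_ratio))
        cand <- which(d < cutoff)
        if (length(cand) == 0L) break
        i <- cand[which.min(d[cand])]
        s <- merge_pair(s, i)
      }
      if (nrow(s) == n_before) break
    }
    out[[key]] <- s
  }
  merged <- do.call(rbind, out)
  rownames(merged) <- NULL
  segment_profile(merged, sample_id = sp$sample_id, merged = TRUE,
                  cna_cutoff_used = cutoff)
}
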
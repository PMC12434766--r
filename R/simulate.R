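# Synthetic-data generator with known truth, plus independent brute-force
# oracles used for testing the pipeline.

#' Define a clonal truth specification
#'
#' Describes a synthetic FFPE tumour for the simulator: a genome layout, a
#' clonal integer-copy-number segment structure that partitions every arm,
#' a tumour fraction diluting that signal into a diploid background, a
#' tumour ploidy (the ratio reference level), per-bin depth, negative
#' binomial overdispersion and GC-bias amplitude.
#'
#' @param layout A `genome_layout`.
#' @param clonal_segments Data frame `chromosome`, `start`, `end`, `cn`
#'   (integer 0..8). Segments must exactly partition each arm.
#' @param tumor_fraction Tumour fraction in \[0, 1\].
#' @param ploidy Tumour ploidy used as the ratio reference (default 2).
#' @param depth Expected read count per full-width bin (default 7500, i.e.
#'   about 1.5X with 100 bp reads and 500 kb bins).
#' @param nb_dispersion Variance inflation over Poisson (default 1.5,
#'   mimicking FFPE overdispersion; 1 = Poisson).
#' @param gc_bias_amplitude Amplitude of the unimodal GC-bias curve
#'   (default 0.3).
#' @param seed Integer seed owned by this spec.
#' @return Object of class `truth_spec`.
#' @export
truth_spec <- function(layout, clonal_segments, tumor_fraction, ploidy = 2,
                       depth = 7500, nb_dispersion = 1.5,
                       gc_bias_amplitude = 0.3, seed = 1) {
  stopifnot(inherits(layout, "genome_layout"))
  need <- c("chromosome", "start", "end", "cn")
  stopifnot(is.data.frame(clonal_segments), all(need %in% names(clonal_segments)))
  cs <- clonal_segments[, need]
  if (any(cs$cn != floor(cs$cn)) || any(cs$cn < 0) || any(cs$cn > 8))
    stop2("cn must be integers in [0, 8]")
  if (!(tumor_fraction >= 0 && tumor_fraction <= 1))
    stop2("tumor_fraction must be in [0, 1]")
  # every arm must be exactly partitioned
  for (i in seq_len(nrow(layout$arms))) {
    a <- layout$arms[i, ]
    s <- cs[cs$chromosome == a$chromosome & cs$start >= a$start &
            cs$end <= a$end, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) == 0L || s$start[1] != a$start || s$end[nrow(s)] != a$end ||
        (nrow(s) > 1L && any(s$end[-nrow(s)] != s$start[-1])))
      stop2("clonal segments do not partition arm ", a$chromosome, a$arm)
  }
  covered <- sum(cs$end - cs$start)
  if (covered != sum(layout$arms$end - layout$arms$start))
    stop2("clonal segments extend outside arms or overlap")
  structure(list(layout = layout, clonal_segments = cs,
                 tumor_fraction = tumor_fraction, ploidy = ploidy,
                 depth = depth, nb_dispersion = nb_dispersion,
                 gc_bias_amplitude = gc_bias_amplitude,
                 seed = as.integer(seed)),
            class = "truth_spec")
}

# Smooth unimodal GC-bias curve, peaked at GC 0.45, range [1-a, 1+a].
gc_bias_curve <- function(gc, amplitude) {
  1 - amplitude + 2 * amplitude * exp(-((gc - 0.45)^2) / (2 * 0.06^2))
}

# Deterministic synthetic GC content: a smooth function of genomic
# position in [0.35, 0.60]. GC is a property of the bin, not the sample,
# so every profile simulated on the same bins shares the same track
# (essential for in-silico mixing of tumour and normal counts).
synthetic_gc <- function(bins) {
  mid <- (bins$start + bins$end) / 2
  chr_idx <- as.integer(factor(bins$chromosome, levels = unique(bins$chromosome)))
  0.475 + 0.125 * sin(2 * pi * mid / 8.1e6 + 1.7 * chr_idx)
}

#' Simulate a binned shallow-WGS count profile from a truth spec
#'
#' Per-bin expected counts are
#' `depth * g(gc) * (t*n + 2*(1-t)) / (t*psi + 2*(1-t))`, scaled by bin
#' width for truncated bins, where `g` is a smooth unimodal GC-bias curve;
#' counts are drawn negative-binomially with the spec's variance inflation.
#' Bit-identical for the same spec (all randomness flows from `spec$seed`).
#' The GC track itself is a deterministic smooth function of genomic
#' position: GC is a property of the bin, not the sample, so profiles
#' simulated on the same bins share it (which is what makes in-silico
#' mixing of tumour and normal counts coherent).
#'
#' @param spec A [truth_spec()].
#' @param bin_size Bin width passed to [make_bins()].
#' @return List with `profile` (raw-stage [bin_profile()], GC and
#'   mappability filled in) and `truth` (the spec, the brute-force
#'   `true_lga_count`, and `expected_segment_ratios`).
#' @export
simulate_profile <- function(spec, bin_size = 5e5) {
  stopifnot(inherits(spec, "truth_spec"))
  bins <- make_bins(spec$layout, bin_size)
  n_bins <- nrow(bins)
  cs <- spec$clonal_segments
  t <- spec$tumor_fraction
  mid <- (bins$start + bins$end) / 2
  cn <- integer(n_bins)
  for (chr in unique(bins$chromosome)) {
    sel <- bins$chromosome == chr
    s <- cs[cs$chromosome == chr, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    idx <- findInterval(mid[sel], s$start)
    stopifnot(all(idx >= 1L), all(mid[sel] < s$end[idx]))
    cn[sel] <- s$cn[idx]
  }
  denom <- t * spec$ploidy + 2 * (1 - t)
  gc <- synthetic_gc(bins)
  g <- gc_bias_curve(gc, spec$gc_bias_amplitude)
  mu <- spec$depth * g * (t * cn + 2 * (1 - t)) / denom *
    (bins$end - bins$start) / bin_size
  counts <- with_seed(spec$seed, {
    if (spec$nb_dispersion > 1) {
      size <- mu / (spec$nb_dispersion - 1)
      ifelse(mu <= 0, 0, stats::rnbinom(n_bins, mu = mu, size = size))
    } else {
      ifelse(mu <= 0, 0, stats::rpois(n_bins, mu))
    }
  })
  bins$gc <- gc
  bins$mappability <- 1
  profile <- bin_profile(bins, counts,
                         sample_id = sprintf("sim_seed%d", spec$seed),
                         stage = "raw")
  expected <- cs
  expected$expected_ratio <- expected_log2_ratio(cs$cn, t, spec$ploidy)
  truth <- list(spec = spec,
                true_lga_count = truth_lga_oracle(spec),
                expected_segment_ratios = expected)
  list(profile = profile, truth = truth)
}

#' Brute-force LGA truth oracle
#'
#' Independent re-implementation of the LGA definition applied directly to
#' the clonal truth segments (no shared code with [call_lgas()]): per arm,
#' consecutive runs of equal copy number are collapsed, then every adjacent
#' pair of truth segments is counted when both flanks are strictly longer
#' than `min_len`, the gap is strictly below `max_gap`, and the copy number
#' changes (or, when `min_delta` is given, the expected-ratio difference
#' reaches it).
#'
#' @param spec A [truth_spec()].
#' @param min_len Minimum flank length (strict `>`, default 10 Mb).
#' @param max_gap Maximum gap (strict `<`, default 3 Mb); truth segments
#'   abut, so the gap is 0.
#' @param min_delta Optional minimum |expected log2-ratio difference|.
#' @return Integer LGA count.
#' @export
truth_lga_oracle <- function(spec, min_len = 1e7, max_gap = 3e6,
                             min_delta = NULL) {
  stopifnot(inherits(spec, "truth_spec"))
  cs <- spec$clonal_segments
  t <- spec$tumor_fraction
  count <- 0L
  for (i in seq_len(nrow(spec$layout$arms))) {
    a <- spec$layout$arms[i, ]
    s <- cs[cs$chromosome == a$chromosome & cs$start >= a$start &
            cs$end <= a$end, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) < 2L) next
    # collapse equal-cn runs
    runs <- list(s[1, ])
    for (j in 2:nrow(s)) {
      last <- runs[[length(runs)]]
      if (s$cn[j] == last$cn && s$start[j] == last$end) {
        runs[[length(runs)]]$end <- s$end[j]
      } else {
        runs[[length(runs) + 1L]] <- s[j, ]
      }
    }
    if (length(runs) < 2L) next
    for (j in seq_len(length(runs) - 1L)) {
      left <- runs[[j]]; right <- runs[[j + 1L]]
      gap <- right$start - left$end
      big_enough <- (left$end - left$start) > min_len &&
        (right$end - right$start) > min_len
      if (!big_enough || gap >= max_gap) next
      qualifies <- if (is.null(min_delta)) left$cn != right$cn
      else abs(expected_log2_ratio(left$cn, t, spec$ploidy) -
               expected_log2_ratio(right$cn, t, spec$ploidy)) >= min_delta
      if (qualifies) count <- count + 1L
    }
  }
  count
}

#' Draw a random clonal truth spec
#'
#' Generates a randomized truth spec for property-style testing: each arm
#' is cut into segments with lengths drawn from `seg_lengths_mb` (a
#' remainder shorter than 13 Mb is folded into the previous segment so no
#' flank lands near the 10 Mb LGA threshold), and copy numbers follow a
#' return-to-diploid walk over `cn_states` (from 2 the walk steps to a
#' random non-diploid state and always steps back), so adjacent truth
#' segments always differ in copy number and the genome-median copy stays
#' diploid.
#'
#' @param layout A `genome_layout`.
#' @param tumor_fraction Tumour fraction of the spec.
#' @param seed Integer seed (also the spec's simulation seed).
#' @param depth,nb_dispersion,gc_bias_amplitude Passed to [truth_spec()].
#' @param seg_lengths_mb Candidate segment lengths in Mb.
#' @param cn_states Copy states of the walk; must contain 2.
#' @return A [truth_spec()].
#' @export
random_truth_spec <- function(layout, tumor_fraction, seed, depth = 7500,
                              nb_dispersion = 1.5, gc_bias_amplitude = 0.3,
                              seg_lengths_mb = c(6, 14, 18, 22, 26),
                              cn_states = c(1, 2, 3)) {
  stopifnot(2 %in% cn_states, length(cn_states) >= 2)
  non_diploid <- setdiff(cn_states, 2)
  segs <- with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(layout$arms))) {
      a <- layout$arms[i, ]
      lens <- numeric(0)
      remaining <- a$end - a$start
      while (remaining >= 13e6) {
        l <- sample(seg_lengths_mb, 1) * 1e6
        if (l > remaining - 13e6 && l != remaining) {
          l <- remaining            # close out the arm
        }
        lens <- c(lens, l)
        remaining <- remaining - l
      }
      if (remaining > 0) {
        if (length(lens) == 0L) lens <- remaining
        else lens[length(lens)] <- lens[length(lens)] + remaining
      }
      cn <- integer(length(lens))
      state <- 2L
      for (k in seq_along(lens)) {
        cn[k] <- state
        state <- if (state == 2L) sample(non_diploid, 1) else 2L
      }
      starts <- a$start + cumsum(c(0, lens[-length(lens)]))
      out[[i]] <- data.frame(chromosome = a$chromosome, start = starts,
                             end = starts + lens, cn = cn,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  truth_spec(layout, segs, tumor_fraction = tumor_fraction, depth = depth,
             nb_dispersion = nb_dispersion,
             gc_bias_amplitude = gc_bias_amplitude, seed = seed)
}

#' Build a symmetric synthetic genome layout
#'
#' Convenience constructor for simulation studies: `n_chromosomes`
#' metacentric chromosomes, each with a p and q arm of `arm_length` bp.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param arm_length Arm length in bp.
#' @return A `genome_layout`.
#' @export
toy_genome <- function(n_chromosomes = 12, arm_length = 55e6) {
  arms <- do.call(rbind, lapply(seq_len(n_chromosomes), function(i)
    data.frame(chromosome = sprintf("c%02d", i),
               start = c(0, arm_length), end = c(arm_length, 2 * arm_length),
               arm = c("p", "q"), stringsAsFactors = FALSE)))
  load_layout(arms, build_label = sprintf("synthetic-%dx%.0fMb",
                                          n_chromosomes, 2 * arm_length / 1e6))
}

#' Reference truth specs for instability studies
#'
#' Two canned clonal designs on a symmetric layout, used for the in-silico
#' dilution study. `"high"` is an unambiguously unstable genome: every arm
#' carries a gain (2-3-2) or a deletion (2-1-2) in bin-aligned thirds, for
#' 2 breaks per arm (48 LGAs on the default 12-chromosome layout, wGI score
#' +28), all at robust single-copy contrast. `"borderline"` carries exactly
#' `baseline` (20) breaks: deletions and low-copy gains provide 14 robust
#' breaks and six 4-to-5 transitions provide marginal ones whose log-ratio
#' contrast shrinks toward the minimal CNA cutoff as tumour fraction falls;
#' it also uses heavy FFPE-like overdispersion, so its score sits exactly
#' at the positivity boundary and degrades first under dilution.
#'
#' @param layout A symmetric layout from [toy_genome()].
#' @param kind `"high"` or `"borderline"`.
#' @param tumor_fraction Tumour fraction of the spec (default 0.6).
#' @param seed Simulation seed.
#' @param nb_dispersion Variance inflation; defaults to 1.5 for `"high"`
#'   and 36 (heavily degraded FFPE) for `"borderline"`.
#' @return A [truth_spec()].
#' @export
instability_reference_spec <- function(layout, kind = c("high", "borderline"),
                                       tumor_fraction = 0.6, seed = 1,
                                       nb_dispersion = NULL) {
  kind <- match.arg(kind)
  arms <- layout$arms
  arm_len <- unique(arms$end - arms$start)
  if (length(arm_len) != 1L)
    stop2("instability_reference_spec needs a symmetric layout (toy_genome)")
  third <- round(arm_len / 3 / 5e5) * 5e5
  mk_arm <- function(i, pattern) {
    lens <- c(third, third, arm_len - 2 * third)
    starts <- arms$start[i] + cumsum(c(0, lens[-3]))
    data.frame(chromosome = arms$chromosome[i], start = starts,
               end = starts + lens, cn = pattern, stringsAsFactors = FALSE)
  }
  n_arms <- nrow(arms)
  patterns <- if (kind == "high") {
    rep(list(c(2, 3, 2), c(2, 1, 2)), length.out = n_arms)
  } else {
    if (n_arms < 10) stop2("borderline design needs at least 10 arms")
    c(rep(list(c(2, 1, 2)), 4), rep(list(c(2, 4, 5)), 6),
      rep(list(c(2, 2, 2)), n_arms - 10))
  }
  segs <- do.call(rbind, lapply(seq_len(n_arms), function(i)
    mk_arm(i, patterns[[i]])))
  nb_dispersion <- nb_dispersion %||% if (kind == "high") 1.5 else 36
  truth_spec(layout, segs, tumor_fraction = tumor_fraction,
             nb_dispersion = nb_dispersion, seed = seed)
}

#' Flat diploid spec on the same layout (simulated matched normal)
#'
#' @param layout A `genome_layout`.
#' @param seed Simulation seed.
#' @param depth,nb_dispersion Passed to [truth_spec()].
#' @return A [truth_spec()] with copy number 2 everywhere and tumour
#'   fraction 0.
#' @export
normal_reference_spec <- function(layout, seed = 1, depth = 7500,
                                  nb_dispersion = 1.5) {
  arms <- layout$arms
  segs <- data.frame(chromosome = arms$chromosome, start = arms$start,
                     end = arms$end, cn = 2, stringsAsFactors = FALSE)
  truth_spec(layout, segs, tumor_fraction = 0, depth = depth,
             nb_dispersion = nb_dispersion, seed = seed)
}

#' Simulate an annotated cohort with known truth
#'
#' Draws per-sample QC, BRCA1/2 and genomic-instability truth for cohort
#' level testing. Default rates emulate an ovarian-cancer FFPE cohort:
#' ~5% QC failure, ~16% BRCA-mutation carriage, and wGI positivity of 75%
#' among carriers versus 40.5% among wild-type samples. Each sample also
#' receives a small annotated variant table (a deleterious BRCA variant for
#' carriers, plus a VUS and a common benign variant) and a true LGA count
#' consistent with its wGI status.
#'
#' @param n_samples Number of samples.
#' @param p_brca P(BRCA-positive).
#' @param p_wgi_brca,p_wgi_wt P(wGI-positive) within BRCA-mutated and
#'   wild-type strata.
#' @param p_qc_fail P(QC failure).
#' @param baseline wGI scaling baseline used to place LGA counts.
#' @param seed Integer seed.
#' @return List with `truth` (data frame: `sample_id`, `qc_pass`,
#'   `brca_positive`, `wgi_positive`, `lga_count`) and `variants` (named
#'   list of per-sample variant data frames).
#' @export
simulate_cohort <- function(n_samples, p_brca = 0.164, p_wgi_brca = 0.75,
                            p_wgi_wt = 0.405, p_qc_fail = 0.052,
                            baseline = 20, seed = 1) {
  stopifnot(n_samples >= 1,
            all(c(p_brca, p_wgi_brca, p_wgi_wt, p_qc_fail) >= 0),
            all(c(p_brca, p_wgi_brca, p_wgi_wt, p_qc_fail) <= 1))
  with_seed(seed, {
    ids <- sprintf("S%03d", seq_len(n_samples))
    qc_pass <- stats::runif(n_samples) >= p_qc_fail
    brca_pos <- stats::runif(n_samples) < p_brca
    p_wgi <- ifelse(brca_pos, p_wgi_brca, p_wgi_wt)
    wgi_pos <- stats::runif(n_samples) < p_wgi
    lga <- ifelse(wgi_pos,
                  baseline + stats::rpois(n_samples, 8),
                  pmin(stats::rpois(n_samples, 10), baseline - 1))
    variants <- vector("list", n_samples)
    names(variants) <- ids
    for (i in seq_len(n_samples)) {
      v <- data.frame(
        gene = c("BRCA1", "TP53"),
        vaf = c(stats::runif(1, 0.2, 0.5), stats::runif(1, 0.3, 0.6)),
        pop_freq = c(0, 0.02),
        classification = c("vus", "benign"),
        variant_id = paste0(ids[i], "_bg", 1:2),
        stringsAsFactors = FALSE)
      if (brca_pos[i]) {
        v <- rbind(data.frame(
          gene = sample(c("BRCA1", "BRCA2"), 1),
          vaf = stats::runif(1, 0.1, 0.6), pop_freq = 0,
          classification = sample(c("deleterious", "suspected_deleterious"), 1),
          variant_id = paste0(ids[i], "_path"),
          stringsAsFactors = FALSE), v)
      }
      variants[[i]] <- v
    }
    list(truth = data.frame(sample_id = ids, qc_pass = qc_pass,
                            brca_positive = brca_pos, wgi_positive = wgi_pos,
                            lga_count = as.integer(lga),
                            stringsAsFactors = FALSE),
         variants = variants)
  })
}
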
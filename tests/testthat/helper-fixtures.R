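# Shared fixture builders. Everything is generated in code at test time.

# Two-armed single-chromosome layout: c1 p=[0,1e6) q=[1e6,2e6).
small_layout <- function() {
  load_layout(data.frame(chromosome = "c1", start = c(0, 1e6),
                         end = c(1e6, 2e6), arm = c("p", "q")))
}

# A normalized-stage profile with given per-bin log2 ratios on one arm.
ratio_profile <- function(ratios, arm_length = length(ratios) * 5e5,
                          bin_size = 5e5) {
  layout <- load_layout(data.frame(chromosome = "c1", start = 0,
                                   end = arm_length, arm = "p"))
  bins <- make_bins(layout, bin_size)
  stopifnot(nrow(bins) == length(ratios))
  bin_profile(bins, rep(100L, length(ratios)), corrected = rep(100, length(ratios)),
              log2_ratio = ratios, stage = "normalized")
}

# One-segment profile covering a ratio vector (for noise_index tests).
single_segment_profile <- function(n_bins, bin_size = 5e5) {
  segment_profile(data.frame(chromosome = "c1", arm = "p", start = 0,
                             end = n_bins * bin_size, n_bins = n_bins,
                             bin_bp = n_bins * bin_size, mean_ratio = 0))
}

# Hand-built merged segment profile from (start, end, mean) rows, one arm.
merged_profile <- function(df, cutoff = 0.25, chromosome = "c1", arm = "p") {
  segment_profile(data.frame(chromosome = chromosome, arm = arm,
                             start = df$start, end = df$end,
                             n_bins = pmax(1, (df$end - df$start) / 5e5),
                             bin_bp = df$end - df$start,
                             mean_ratio = df$mean),
                  merged = TRUE, cna_cutoff_used = cutoff)
}

# Write a small SAM fixture and convert to an indexed BAM.
# Reads are 50M, paired; only flags/mapq/position matter to the counter.
make_bam_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sam <- file.path(dir, "fixture.sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           "@SQ\tSN:c1\tLN:2000000",
           "@SQ\tSN:c2\tLN:1000000")
  seq50 <- paste(rep("A", 50), collapse = "")
  mk <- function(name, chrom, pos, flag, mapq) {
    sprintf("%s\t%d\t%s\t%d\t%d\t50M\t=\t%d\t150\t%s\t*",
            name, flag, chrom, pos, mapq, pos + 100, seq50)
  }
  # 10 counted reads: bin1 [0,5e5): 3; bin2: 2; bin3 [1e6,1.5e6): 3; bin4: 2
  body <- c(
    mk("r01", "c1", 100, 99, 60),
    mk("r02", "c1", 2000, 99, 60),
    mk("x_notproper", "c1", 2500, 65, 60),   # paired but not proper-paired
    mk("x_dup", "c1", 3000, 1123, 60),       # duplicate flag set
    mk("x_lowmq", "c1", 4000, 99, 5),        # below MAPQ floor
    mk("r03", "c1", 499951, 99, 60),         # leftmost in bin1 despite overlap
    mk("r04", "c1", 500001, 99, 60),
    mk("r05", "c1", 700000, 99, 60),
    mk("r06", "c1", 1000001, 99, 60),
    mk("r07", "c1", 1200000, 99, 60),
    mk("r08", "c1", 1400000, 99, 60),
    mk("r09", "c1", 1600000, 99, 60),
    mk("r10", "c1", 1900000, 99, 60),
    mk("ignored_c2", "c2", 100, 99, 60))     # passes filters, outside bins
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "fixture"), overwrite = TRUE)
  bam
}

expected_fixture_counts <- c(3, 2, 3, 2)
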
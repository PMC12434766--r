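test_that("truth specs validate their clonal partition", {
  layout <- toy_genome(1, 3e7)
  good <- data.frame(chromosome = "c01", start = c(0, 3e7), end = c(3e7, 6e7),
                     cn = c(2, 3))
  expect_s3_class(truth_spec(layout, good, 0.5), "truth_spec")
  gap <- data.frame(chromosome = "c01", start = c(0, 3.5e7), end = c(3e7, 6e7),
                    cn = c(2, 3))
  expect_error(truth_spec(layout, gap, 0.5), "partition")
  expect_error(truth_spec(layout, transform(good, cn = c(2, 9)), 0.5), "cn")
  expect_error(truth_spec(layout, good, 1.5), "tumor_fraction")
})

test_that("simulation is deterministic and respects the count model", {
  layout <- toy_genome(2, 3e7)
  spec <- random_truth_spec(layout, 0.6, seed = 5)
  s1 <- simulate_profile(spec)
  s2 <- simulate_profile(spec)
  expect_identical(s1$profile$raw_count, s2$profile$raw_count)
  expect_identical(s1$profile$bins$gc, s2$profile$bins$gc)

  # tumour fraction 0: flat expectation regardless of clonal structure
  spec0 <- truth_spec(layout, spec$clonal_segments, tumor_fraction = 0, seed = 5)
  expect_true(all(simulate_profile(spec0)$truth$expected_segment_ratios$expected_ratio == 0))
})

test_that("a pure-tumour CN-4 region lands at log2 ratio 1", {
  layout <- toy_genome(5, 5e7)           # 1000 bins
  arms <- layout$arms
  segs <- data.frame(chromosome = arms$chromosome, start = arms$start,
                     end = arms$end, cn = 2)
  segs$cn[1] <- 4
  spec <- truth_spec(layout, segs, tumor_fraction = 1, seed = 8)
  sim <- simulate_profile(spec)
  expect_equal(sim$truth$expected_segment_ratios$expected_ratio[1], 1)
  norm <- normalize_profile(sim$profile)
  sel <- norm$bins$chromosome == "c01" & norm$bins$arm == "p" & norm$bins$usable
  expect_equal(mean(norm$log2_ratio[sel]), 1, tolerance = 0.05)
})

test_that("the GC bias injected by the simulator is removed by normalisation", {
  layout <- toy_genome(6, 55e6)
  spec <- random_truth_spec(layout, 0.6, seed = 17)
  sim <- simulate_profile(spec)
  raw_cor <- cor(log2(sim$profile$raw_count), sim$profile$bins$gc)
  expect_gt(abs(raw_cor), 0.2)           # bias is really there before
  norm <- normalize_profile(sim$profile)
  u <- norm$bins$usable
  expect_lt(abs(cor(norm$log2_ratio[u], norm$bins$gc[u])), 0.05)
})

test_that("the truth oracle applies the LGA rule literally", {
  layout <- toy_genome(1, 6e7)
  flat <- data.frame(chromosome = "c01", start = c(0, 6e7), end = c(6e7, 1.2e8),
                     cn = c(2, 2))
  expect_equal(truth_lga_oracle(truth_spec(layout, flat, 0.6)), 0)
  # three qualifying breaks on one arm
  segs <- data.frame(chromosome = "c01",
                     start = c(0, 1.5e7, 3e7, 4.5e7, 6e7),
                     end = c(1.5e7, 3e7, 4.5e7, 6e7, 1.2e8),
                     cn = c(2, 3, 2, 3, 2))
  expect_equal(truth_lga_oracle(truth_spec(layout, segs, 0.6)), 3)
  # a flank of exactly 10 Mb fails the strict inequality
  segs10 <- data.frame(chromosome = "c01",
                       start = c(0, 1e7, 6e7), end = c(1e7, 6e7, 1.2e8),
                       cn = c(3, 2, 2))
  expect_equal(truth_lga_oracle(truth_spec(layout, segs10, 0.6)), 0)
  # equal-cn neighbours collapse before counting
  segs_eq <- data.frame(chromosome = "c01",
                        start = c(0, 1.5e7, 3e7, 6e7),
                        end = c(1.5e7, 3e7, 6e7, 1.2e8),
                        cn = c(2, 2, 3, 2))
  expect_equal(truth_lga_oracle(truth_spec(layout, segs_eq, 0.6)), 1)
})

test_that("oracle and caller agree exactly on noiseless pre-made segment profiles", {
  layout <- toy_genome(3, 55e6)
  for (s in 1:10) {
    spec <- random_truth_spec(layout, tumor_fraction = 0.6, seed = 600 + s)
    cs <- spec$clonal_segments
    arm <- ifelse(cs$start < 55e6, "p", "q")
    sp <- segment_profile(data.frame(
      chromosome = cs$chromosome, arm = arm, start = cs$start, end = cs$end,
      n_bins = (cs$end - cs$start) / 5e5, bin_bp = cs$end - cs$start,
      mean_ratio = expected_log2_ratio(cs$cn, 0.6, 2)),
      merged = TRUE, cna_cutoff_used = 0.1)
    expect_equal(nrow(call_lgas(sp)), truth_lga_oracle(spec))
  }
})

test_that("cohorts are reproducible and hit their BRCA rate", {
  co1 <- simulate_cohort(100, p_brca = 0.16, seed = 99)
  co2 <- simulate_cohort(100, p_brca = 0.16, seed = 99)
  expect_identical(co1, co2)
  n_brca <- sum(co1$truth$brca_positive)
  expect_gte(n_brca, qbinom(0.005, 100, 0.16))
  expect_lte(n_brca, qbinom(0.995, 100, 0.16))
  # carriers get a deleterious variant fixture, wild-types do not
  for (i in seq_len(10)) {
    v <- co1$variants[[i]]
    has_path <- any(v$classification %in% c("deleterious", "suspected_deleterious"))
    expect_equal(has_path, co1$truth$brca_positive[i])
  }
  none <- simulate_cohort(50, p_brca = 0, p_wgi_brca = 0, p_wgi_wt = 0, seed = 1)
  expect_false(any(none$truth$brca_positive))
  expect_false(any(none$truth$wgi_positive))
  expect_true(all(none$truth$lga_count < 20))
})
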
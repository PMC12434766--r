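test_that("expected ratio closed form behaves at its anchors", {
  # neutral segments are ratio-0 at ploidy 2 for any tumour fraction
  for (t in seq(0.05, 1, by = 0.05))
    expect_equal(expected_log2_ratio(2, t, 2), 0)
  expect_equal(expected_log2_ratio(4, 1, 2), 1)
  expect_equal(expected_log2_ratio(0, 1, 2), -Inf)
  expect_equal(expected_log2_ratio(3, 0.6, 2), log2(2.6 / 2))
})

test_that("a flat profile is flagged unidentifiable at the grid floor", {
  sp <- segment_profile(data.frame(
    chromosome = paste0("c", 1:6), arm = "p", start = 0, end = 2e7,
    n_bins = 40, bin_bp = 2e7, mean_ratio = rnorm(6, 0, 0.005)))
  tf <- estimate_tf(sp)
  expect_true(tf$floor_flag)
  expect_equal(tf$fraction, 0.05)
})

test_that("tumour fraction is recovered from clonal simulations", {
  layout <- toy_genome(6, 55e6)
  for (t in c(0.2, 0.6)) {
    spec <- random_truth_spec(layout, tumor_fraction = t, seed = 500 + 100 * t)
    sim <- simulate_profile(spec)
    frag <- run_wgi(sim$profile, layout)
    expect_lte(abs(frag$tf$fraction - t), 0.05)
    expect_false(frag$tf$floor_flag)
  }
})

test_that("estimate_tf enforces its input preconditions", {
  sp <- segment_profile(data.frame(chromosome = "c1", arm = "p", start = 0,
                                   end = 2e7, n_bins = 40, bin_bp = 2e7,
                                   mean_ratio = 0))
  expect_error(estimate_tf(sp), "too few")
})

test_that("dilution at alpha = 1 is the identity and is seed-deterministic", {
  layout <- toy_genome(2, 2e7)
  tum <- simulate_profile(instability_reference_spec(toy_genome(12, 55e6),
                                                     "high", seed = 3))$profile
  nor <- simulate_profile(normal_reference_spec(toy_genome(12, 55e6),
                                                seed = 4))$profile
  same <- dilute_counts(tum, nor, 0.6, 0.6, seed = 9)
  expect_identical(same$raw_count, tum$raw_count)
  d1 <- dilute_counts(tum, nor, 0.6, 0.3, seed = 9)
  d2 <- dilute_counts(tum, nor, 0.6, 0.3, seed = 9)
  expect_identical(d1$raw_count, d2$raw_count)
  d3 <- dilute_counts(tum, nor, 0.6, 0.3, seed = 10)
  expect_false(identical(d1$raw_count, d3$raw_count))
  expect_error(dilute_counts(tum, nor, 0.4, 0.6, seed = 1), "up-dilute")
})

test_that("dilution shrinks a CN-4 region to its closed-form expectation", {
  layout <- toy_genome(5, 5e7)           # 1000 bins at 500 kb
  arms <- layout$arms
  segs <- data.frame(chromosome = arms$chromosome, start = arms$start,
                     end = arms$end, cn = 2)
  segs$cn[1] <- 4                        # c01 p arm is a CN-4 gain
  spec <- truth_spec(layout, segs, tumor_fraction = 0.6, seed = 11)
  tum <- simulate_profile(spec)$profile
  nor <- simulate_profile(normal_reference_spec(layout, seed = 12))$profile
  region_mean <- function(prof) {
    norm <- normalize_profile(prof)
    sel <- norm$bins$chromosome == "c01" & norm$bins$arm == "p" & norm$bins$usable
    mean(norm$log2_ratio[sel])
  }
  expect_equal(region_mean(tum), log2(1.6), tolerance = 0.05 / log2(1.6))
  dil <- dilute_counts(tum, nor, 0.6, 0.3, seed = 13)
  expect_equal(region_mean(dil), log2(1.3), tolerance = 0.05 / log2(1.3))
})

test_that("dilution conserves expected total depth", {
  layout <- toy_genome(4, 5e7)
  spec <- instability_reference_spec(toy_genome(12, 55e6), "high", seed = 21)
  tum <- simulate_profile(spec)$profile
  nor <- simulate_profile(normal_reference_spec(toy_genome(12, 55e6),
                                                seed = 22))$profile
  alpha <- 0.5
  mix <- dilute_counts(tum, nor, 0.6, 0.3, seed = 23)
  expected_total <- alpha * sum(tum$raw_count) + (1 - alpha) * sum(nor$raw_count)
  expect_equal(sum(mix$raw_count), expected_total,
               tolerance = 3 * sqrt(expected_total) / expected_total)
})

test_that("the dilution series reports per-level results and a stability floor", {
  layout <- toy_genome(12, 55e6)
  spec <- instability_reference_spec(layout, "high", seed = 31)
  tum <- simulate_profile(spec)$profile
  nor <- simulate_profile(normal_reference_spec(layout, seed = 32))$profile
  res <- dilution_series(tum, nor, 0.6, c(0.5, 0.3), layout, seed = 31)
  expect_equal(res$target_tf, c(0.5, 0.3))
  expect_equal(attr(res, "undiluted_status"), "positive")
  expect_true(all(res$status == "positive"))
  expect_equal(attr(res, "stability_floor"), 0.3)
  empty <- dilution_series(tum, nor, 0.6, numeric(0), layout, seed = 31)
  expect_equal(nrow(empty), 0)
  expect_error(dilution_series(tum, nor, 0.6, c(0.3, 0.5), layout, seed = 1),
               "descending")
})
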
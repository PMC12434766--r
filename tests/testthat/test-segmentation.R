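# Exhaustive minimiser over all partitions with a minimum segment size:
# the independent oracle for the penalized optimal-partitioning search.
brute_force_partition_cost <- function(r, penalty, min_seg = 3L) {
  n <- length(r)
  compositions <- function(n) {
    if (n == 0) return(list(integer(0)))
    out <- list()
    for (first in min_seg:n) {
      if (n - first != 0 && n - first < min_seg) next
      for (rest in compositions(n - first)) out[[length(out) + 1]] <- c(first, rest)
    }
    out
  }
  best <- Inf
  for (comp in compositions(n)) {
    ends <- cumsum(comp)
    starts <- c(1, head(ends, -1) + 1)
    cost <- sum(mapply(function(a, b) sum((r[a:b] - mean(r[a:b]))^2), starts, ends)) +
      penalty * (length(comp) - 1)
    best <- min(best, cost)
  }
  best
}

dp_cost <- function(r, ids, penalty) {
  sum(tapply(r, ids, function(x) sum((x - mean(x))^2))) +
    penalty * (length(unique(ids)) - 1)
}

test_that("segmentation attains the exhaustive-search optimum on short arms", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(6:12, 1)
    r <- rnorm(n, 0, 0.1) + sample(c(0, 0.8), 1) * (seq_len(n) > n / 2)
    penalty <- runif(1, 0.01, 0.5)
    ids <- wgiscore:::optimal_partition(r, penalty, min_seg = 3L)
    expect_equal(dp_cost(r, ids, penalty),
                 brute_force_partition_cost(r, penalty), tolerance = 1e-9)
  }
})

test_that("flat profiles yield one segment per arm", {
  layout <- toy_genome(2, 2e7)
  bins <- make_bins(layout, 5e5)
  bins$gc <- 0.5
  prof <- normalize_profile(bin_profile(bins, rep(1000L, nrow(bins))))
  sp <- segment_bins(prof)
  expect_equal(nrow(sp$segments), 4)   # one per arm
  expect_false(sp$merged)
})

test_that("a clean step is localised within one bin", {
  set.seed(5)
  r <- c(rnorm(40, 0, 0.05), rnorm(40, 0.6, 0.05))
  prof <- ratio_profile(r)
  sp <- segment_bins(prof)
  expect_equal(nrow(sp$segments), 2)
  expect_lte(abs(sp$segments$start[2] / 5e5 - 40), 1)
})

test_that("minimum segment size forbids two-bin segments at a blip", {
  set.seed(6)
  r <- rnorm(40, 0, 0.05)
  r[20:21] <- r[20:21] + 1.0
  sp <- segment_bins(ratio_profile(r))
  expect_true(all(sp$segments$n_bins >= 3))
})

test_that("the CNA cutoff combines noise and TF terms exactly", {
  c1 <- cna_cutoff(0, 1.0)
  expect_equal(as.numeric(c1), 0.5 * log2(1.5))
  expect_false(attr(c1, "single_copy_flag"))

  c2 <- cna_cutoff(0.10, 0.30)
  expect_equal(as.numeric(c2), 0.25)
  expect_true(attr(c2, "single_copy_flag"))   # 0.25 >= log2(1.15)

  c3 <- cna_cutoff(0.02, 0.60)
  expect_equal(as.numeric(c3), 0.5 * log2(1.3))
  expect_false(attr(c3, "single_copy_flag"))

  expect_error(cna_cutoff(0.1, 0), "fraction")
  expect_gt(as.numeric(cna_cutoff(0, 0.01)), 0)
})

test_that("merging follows absorb-then-closest-pair rules", {
  # single segment: fixpoint
  one <- segment_profile(data.frame(chromosome = "c1", arm = "p", start = 0,
                                    end = 2e7, n_bins = 40, bin_bp = 2e7,
                                    mean_ratio = 0.3))
  m <- merge_segments(one, 0.25)
  expect_equal(nrow(m$segments), 1)
  expect_true(m$merged)

  # two 20 Mb segments 0.10 apart under cutoff 0.25 merge, weighted mean
  two <- segment_profile(data.frame(chromosome = "c1", arm = "p",
                                    start = c(0, 2e7), end = c(2e7, 4e7),
                                    n_bins = c(40, 40), bin_bp = c(2e7, 2e7),
                                    mean_ratio = c(0.00, 0.10)))
  m <- merge_segments(two, 0.25)
  expect_equal(nrow(m$segments), 1)
  expect_equal(m$segments$mean_ratio, 0.05)
  expect_equal(m$segments$end - m$segments$start, 4e7)

  # a 2 Mb spike between flat flanks is absorbed, then everything merges
  spike <- segment_profile(data.frame(chromosome = "c1", arm = "p",
                                      start = c(0, 2e7, 2.2e7),
                                      end = c(2e7, 2.2e7, 4.2e7),
                                      n_bins = c(40, 4, 40),
                                      bin_bp = c(2e7, 2e6, 2e7),
                                      mean_ratio = c(0, 1.0, 0)))
  m <- merge_segments(spike, 0.25)
  expect_equal(nrow(m$segments), 1)
  expect_lt(abs(m$segments$mean_ratio), 0.1)
})

test_that("merging reaches a fixpoint with all surviving gaps >= cutoff", {
  set.seed(31)
  for (rep in 1:10) {
    k <- sample(4:9, 1)
    lens <- sample(c(2e6, 5e6, 1.5e7, 2.5e7), k, replace = TRUE)
    starts <- cumsum(c(0, head(lens, -1)))
    sp <- segment_profile(data.frame(chromosome = "c1", arm = "p",
                                     start = starts, end = starts + lens,
                                     n_bins = pmax(1, lens / 5e5),
                                     bin_bp = lens,
                                     mean_ratio = runif(k, -0.6, 0.6)))
    cutoff <- runif(1, 0.1, 0.4)
    m <- merge_segments(sp, cutoff)
    expect_lte(nrow(m$segments), k)
    s <- m$segments[order(m$segments$start), ]
    if (nrow(s) > 1) {
      expect_true(all(abs(diff(s$mean_ratio)) >= cutoff))
      expect_true(all(s$length >= 3e6 | nrow(s) == 1))
    }
    # partition property: total covered bp is conserved
    expect_equal(sum(s$bin_bp), sum(lens))
  }
})
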
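variant <- function(gene = "BRCA1", vaf = 0.3, pop_freq = 0,
                    classification = "deleterious", id = "v1") {
  data.frame(gene = gene, vaf = vaf, pop_freq = pop_freq,
             classification = classification, variant_id = id,
             stringsAsFactors = FALSE)
}

test_that("variant filtering applies VAF, frequency and classification rules", {
  expect_equal(filter_variants(variant())$status, "positive")
  # low-VAF deleterious variant is excluded
  low <- filter_variants(variant(vaf = 0.04))
  expect_equal(low$status, "negative")
  expect_equal(low$excluded$reason, "low_vaf")
  # common variant is excluded
  common <- filter_variants(variant(pop_freq = 0.002))
  expect_equal(common$status, "negative")
  expect_equal(common$excluded$reason, "common")
  # VUS is retained but not supporting
  vus <- filter_variants(variant(classification = "vus"))
  expect_equal(vus$status, "negative")
  expect_equal(nrow(vus$excluded), 0)
  # non-BRCA deleterious variants never support BRCA status
  expect_equal(filter_variants(variant(gene = "TP53"))$status, "negative")
  # empty list is negative, and status tracks the supporting set
  empty <- filter_variants(NULL)
  expect_equal(empty$status, "negative")
  expect_equal(nrow(empty$supporting_variants), 0)
  # boundary: VAF exactly 5% and frequency exactly 0.1% are retained
  expect_equal(filter_variants(variant(vaf = 0.05, pop_freq = 0.001))$status,
               "positive")
})

test_that("the conjunctive exclusion reading only drops doubly-failing variants", {
  v <- rbind(variant(vaf = 0.04, id = "lowonly"),
             variant(pop_freq = 0.002, id = "commononly"),
             variant(vaf = 0.04, pop_freq = 0.002, id = "both"))
  either <- filter_variants(v)
  expect_equal(either$status, "negative")
  expect_equal(nrow(either$excluded), 3)
  both <- filter_variants(v, exclusion = "both")
  expect_equal(both$status, "positive")
  expect_equal(both$excluded$variant_id, "both")
})

test_that("unannotated variants are excluded with a warning", {
  v <- variant()
  v$pop_freq <- NA_real_
  expect_warning(res <- filter_variants(v), "lack VAF")
  expect_equal(res$status, "negative")
  expect_equal(res$excluded$reason, "unannotated")
})

qc_pass <- wgiscore:::qc_result(TRUE, "targeted", character(0))
qc_fail <- wgiscore:::qc_result(FALSE, "swgs", "mean depth 0.50X not > 1X")
brca_pos <- filter_variants(variant())
brca_neg <- filter_variants(NULL)

test_that("the HRD combination rule follows its truth table", {
  wgi_pos <- wgi_score(23)
  wgi_neg <- wgi_score(10)
  combos <- list(list(brca_pos, wgi_pos, "positive"),
                 list(brca_pos, wgi_neg, "positive"),
                 list(brca_neg, wgi_pos, "positive"),
                 list(brca_neg, wgi_neg, "negative"))
  for (cb in combos) {
    rep <- combine_hrd(qc_pass, qc_pass, cb[[1]], cb[[2]])
    expect_equal(rep$hrd_status, cb[[3]])
  }
  # QC failure forces no_call regardless of markers
  rep <- combine_hrd(qc_pass, qc_fail, brca_pos, NULL)
  expect_equal(rep$hrd_status, "no_call")
  rep <- combine_hrd(qc_fail, qc_pass, brca_pos, wgi_pos)
  expect_equal(rep$hrd_status, "no_call")
  # passing sWGS QC with a missing wGI result is an inconsistent state
  expect_error(combine_hrd(qc_pass, qc_pass, brca_pos, NULL), "inconsistent")
})

test_that("combine_hrd is monotone in its components", {
  # flipping any component negative -> positive never turns the call negative
  for (brca in list(brca_neg, brca_pos))
    for (lga in c(10, 23)) {
      lo <- combine_hrd(qc_pass, qc_pass, brca, wgi_score(lga))$hrd_status
      hi1 <- combine_hrd(qc_pass, qc_pass, brca_pos, wgi_score(lga))$hrd_status
      hi2 <- combine_hrd(qc_pass, qc_pass, brca, wgi_score(23))$hrd_status
      if (lo == "positive") {
        expect_equal(hi1, "positive")
        expect_equal(hi2, "positive")
      }
    }
})

test_that("a low tumour fraction warns without changing the call", {
  tf_low <- structure(list(fraction = 0.2, ploidy = 2, fit_cost = 0,
                           method = "grid", floor_flag = FALSE),
                      class = "tf_estimate")
  rep <- combine_hrd(qc_pass, qc_pass, brca_neg, wgi_score(25), tf = tf_low)
  expect_equal(rep$hrd_status, "positive")
  expect_match(rep$warnings, "TF floor", all = FALSE)
})

test_that("concordance reproduces the published 2x2 arithmetic", {
  test_calls <- c(rep("positive", 13), rep("positive", 1), rep("negative", 13))
  ref_calls <- c(rep("positive", 13), rep("negative", 1), rep("negative", 13))
  res <- concordance(test_calls, ref_calls)
  expect_equal(c(res$tp, res$fp, res$fn, res$tn), c(13, 1, 0, 13))
  expect_equal(res$ppa, 100.0)
  expect_equal(res$npa, 92.9)
  expect_equal(res$opa, 96.3)
  expect_equal(res$n_used, 27)
})

test_that("concordance handles degenerate tables and no_calls", {
  res <- concordance(rep("positive", 10), rep("positive", 10))
  expect_equal(res$ppa, 100.0)
  expect_true(is.na(res$npa))            # no reference negatives: absent
  expect_equal(res$opa, 100.0)
  res <- concordance(c("positive", "no_call", "negative"),
                     c("positive", "positive", "negative"))
  expect_equal(res$n_used, 2)
  expect_equal(res$n_dropped, 1)
  expect_error(concordance(character(0), character(0)), "empty")
  # swapping test and reference swaps the marginals
  a <- concordance(c("positive", "positive", "negative"),
                   c("positive", "negative", "negative"))
  b <- concordance(c("positive", "negative", "negative"),
                   c("positive", "positive", "negative"))
  expect_equal(a$fp, b$fn)
  expect_equal(a$ppa, b$npa)
  expect_equal(a$npa, b$ppa)
})

test_that("cohort summary computes rates and the inclusion-exclusion identity", {
  mk_report <- function(qc_ok, brca, wgi) {
    combine_hrd(qc_pass, if (qc_ok) qc_pass else qc_fail,
                if (brca) brca_pos else brca_neg,
                if (qc_ok) wgi_score(if (wgi) 25 else 10) else NULL)
  }
  reports <- c(lapply(1:4, function(i) mk_report(FALSE, FALSE, FALSE)),
               lapply(1:9, function(i) mk_report(TRUE, TRUE, TRUE)),
               lapply(1:3, function(i) mk_report(TRUE, TRUE, FALSE)),
               lapply(1:26, function(i) mk_report(TRUE, FALSE, TRUE)),
               lapply(1:35, function(i) mk_report(TRUE, FALSE, FALSE)))
  s <- cohort_summary(reports)
  expect_equal(s$n_total, 77)
  expect_equal(s$n_passing, 73)
  expect_equal(s$success_rate, 94.8)
  expect_equal(s$n_hrd_positive, 9 + 3 + 26)
  # inclusion-exclusion: HRD+ = BRCA+ + wGI+ - both
  expect_equal(s$n_hrd_positive, 12 + 35 - 9)
  expect_equal(s$hrd_positive_pct, 52.1)  # 38/73
  expect_equal(s$brca_positive_pct, 16.4) # 12/73
  expect_equal(s$wgi_positive_pct, 47.9)  # 35/73
  expect_equal(s$both_among_hrd_pct, 23.7) # 9/38
  expect_equal(s$wgi_pos_in_brca_wt_pct, 42.6) # 26/61
  expect_equal(s$wgi_pos_in_brca_mut_pct, 75.0) # 9/12
})

test_that("cohort summary reports empty strata as absent", {
  reports <- lapply(1:5, function(i)
    combine_hrd(qc_pass, qc_pass, brca_neg, wgi_score(5)))
  s <- cohort_summary(reports)
  expect_equal(s$hrd_positive_pct, 0)
  expect_true(is.na(s$both_among_hrd_pct))
  expect_true(is.na(s$wgi_pos_in_brca_mut_pct))
})
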
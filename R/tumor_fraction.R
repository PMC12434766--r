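# Grid-search tumour-fraction/ploidy estimation and in-silico dilution.

#' Expected log2 copy ratio of an integer copy-number state
#'
#' Closed form for a clonal tumour at fraction `t` with tumour ploidy `psi`
#' in a diploid normal background:
#' `E(n; t, psi) = log2((t*n + 2*(1-t)) / (t*psi + 2*(1-t)))`.
#' Neutral segments (`n == psi == 2`) have expected ratio 0 at any `t`.
#'
#' @param n Integer copy number(s).
#' @param t Tumour fraction in \[0, 1\].
#' @param psi Tumour ploidy (reference level of the ratio).
#' @return Numeric vector of expected log2 ratios.
#' @export
expected_log2_ratio <- function(n, t, psi = 2) {
  stopifnot(is.numeric(n), is.numeric(t), t >= 0, t <= 1, psi > 0)
  log2((t * n + 2 * (1 - t)) / (t * psi + 2 * (1 - t)))
}

#' Estimate tumour fraction and ploidy by grid search
#'
#' Simplified clonal fit over a (tumour fraction, ploidy) grid: for each
#' candidate `(t, psi)`, every segment is assigned the integer copy number
#' in `0..max_cn` whose expected log2 ratio is nearest its observed mean,
#' and the candidate's cost is the segment-length-weighted sum of squared
#' residuals. Clonal fits are degenerate (a genome-doubled interpretation
#' at reduced tumour fraction reproduces the same segment means), so among
#' candidates within a 5% cost band of the optimum the most parsimonious
#' ploidy (nearest 2) is preferred, then the cost-minimising `t` in that
#' class, exact ties to the smaller `t`. Assigning copy number 0
#' (homozygous deletion) to a segment longer than `homdel_max_len` incurs a
#' large penalty: multi-megabase homozygous deletions are biologically
#' implausible, and the penalty removes the halved-tumour-fraction branch
#' that would otherwise tie.
#'
#' @param sp A [segment_profile()], normally merged.
#' @param t_grid Tumour-fraction grid (default 0.05 to 1.00 step 0.01).
#' @param psi_grid Ploidy grid (default 1.6 to 4.0 step 0.1).
#' @param max_cn Largest integer copy number considered.
#' @param min_segments,min_bins At least `min_segments` segments or
#'   `min_bins` member bins are required.
#' @param homdel_max_len Longest segment allowed to take copy 0 unpenalised.
#' @param homdel_penalty Squared-residual penalty added beyond that length.
#' @param state_penalty Weak prior against extreme copy states: each
#'   segment's cost gains `state_penalty * (n - psi)^2`. This disfavours
#'   the scaled reinterpretations (e.g. states 1/4/7 at high ploidy) whose
#'   denser level lattice would otherwise out-fit the parsimonious branch
#'   by chance; it is two orders of magnitude below typical residuals at
#'   genuinely ambiguous assignments, so it never overrides the data.
#' @return Object of class `tf_estimate` with `fraction`, `ploidy`,
#'   `fit_cost`, `method`, `floor_flag` (`TRUE` when the best fit assigns
#'   every segment the neutral copy state, i.e. no aberration informs the
#'   estimate, or the fit lands on the 5% grid floor).
#' @export
estimate_tf <- function(sp, t_grid = seq(0.05, 1, by = 0.01),
                        psi_grid = seq(1.6, 4, by = 0.1), max_cn = 8,
                        min_segments = 5, min_bins = 500,
                        homdel_max_len = 3e6, homdel_penalty = 10,
                        state_penalty = 1e-3) {
  stopifnot(inherits(sp, "segment_profile"))
  seg <- sp$segments
  if (nrow(seg) < min_segments && sum(seg$n_bins) < min_bins)
    stop2("too few segments/bins for tumour-fraction estimation (",
          nrow(seg), " segments, ", sum(seg$n_bins), " bins)")
  m <- seg$mean_ratio
  w <- seg$length / sum(seg$length)
  pen_row <- seg$length > homdel_max_len
  ns <- 0:max_cn
  t_grid <- sort(t_grid)
  psi_grid <- sort(psi_grid)
  grid <- expand.grid(t = t_grid, psi = psi_grid)
  cost <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    t <- grid$t[g]; psi <- grid$psi[g]
    denom2 <- 2 * (1 - t)
    e <- log2((t * ns + denom2) / (t * psi + denom2))
    d <- (outer(m, e, "-"))^2
    d <- sweep(d, 2, state_penalty * (ns - psi)^2, "+")
    d[pen_row, 1] <- d[pen_row, 1] + homdel_penalty
    rmin <- d[, 1]
    for (k in seq_along(ns)[-1]) rmin <- pmin(rmin, d[, k])
    cost[g] <- sum(w * rmin)
  }
  # Clonal fits carry a whole-genome-doubling degeneracy: the same means
  # are reproduced almost exactly at doubled ploidy and reduced t. Among
  # candidates within a 5% cost band of the optimum, prefer the most
  # parsimonious ploidy (nearest 2), then the cost-minimising t in that
  # class (exact ties to the smaller t).
  band <- which(cost <= min(cost) * 1.05 + 1e-12)
  psi_dist <- abs(grid$psi[band] - 2)
  cls <- band[psi_dist == min(psi_dist)]
  cls <- cls[grid$psi[cls] == min(grid$psi[cls])]
  pick <- cls[order(cost[cls], grid$t[cls])][1]
  best <- list(cost = cost[pick], t = grid$t[pick], psi = grid$psi[pick])
  # recompute the winning assignment for the floor flag
  e <- expected_log2_ratio(ns, best$t, best$psi)
  d <- (outer(m, e, "-"))^2
  d <- sweep(d, 2, state_penalty * (ns - best$psi)^2, "+")
  d[pen_row, 1] <- d[pen_row, 1] + homdel_penalty
  n_hat <- ns[apply(d, 1, which.min)]
  all_neutral <- all(n_hat == round(best$psi))
  if (all_neutral) best$t <- min(t_grid)  # no aberration: TF unidentifiable
  structure(list(fraction = best$t, ploidy = best$psi, fit_cost = best$cost,
                 method = "grid",
                 floor_flag = all_neutral || best$t <= min(t_grid)),
            class = "tf_estimate")
}

#' @export
print.tf_estimate <- function(x, ...) {
  cat(sprintf("tf_estimate: fraction %.2f, ploidy %.1f (cost %.4g)%s\n",
              x$fraction, x$ploidy, x$fit_cost,
              if (x$floor_flag) " [floor: aberration-free or at grid floor]" else ""))
  invisible(x)
}

#' Dilute tumour bin counts with normal counts in silico
#'
#' Binomial count thinning that emulates read-level mixing of tumour and
#' white-blood-cell sWGS libraries at bin resolution: with mixing weight
#' `alpha = target_tf / tumor_tf`, each mixed count is
#' `Binomial(tumor_i, alpha) + Binomial(normal_i, 1 - alpha)`, so the
#' expected mixed ratio follows the alpha-weighted mixture and total depth
#' is conserved in expectation. Deterministic for a fixed seed.
#'
#' @param tumor,normal Raw-stage [bin_profile()]s on the same bin set.
#' @param tumor_tf Tumour fraction of the undiluted tumour profile.
#' @param target_tf Desired tumour fraction, `0 < target_tf <= tumor_tf`.
#' @param seed Integer seed (required).
#' @return A raw-stage `bin_profile` of mixed counts.
#' @export
dilute_counts <- function(tumor, normal, tumor_tf, target_tf, seed) {
  stopifnot(inherits(tumor, "bin_profile"), inherits(normal, "bin_profile"))
  if (missing(seed)) stop2("seed is required")
  if (!(tumor_tf > 0 && tumor_tf <= 1)) stop2("tumor_tf must be in (0, 1]")
  if (!(target_tf > 0)) stop2("target_tf must be positive")
  if (target_tf > tumor_tf)
    stop2("cannot up-dilute: target_tf (", target_tf,
          ") exceeds tumor_tf (", tumor_tf, ")")
  if (nrow(tumor$bins) != nrow(normal$bins) ||
      !all(tumor$bins$chromosome == normal$bins$chromosome) ||
      !all(tumor$bins$start == normal$bins$start))
    stop2("tumor and normal profiles must share the same bin set")
  alpha <- target_tf / tumor_tf
  n <- nrow(tumor$bins)
  mixed <- with_seed(seed, {
    stats::rbinom(n, size = round(tumor$raw_count), prob = alpha) +
      stats::rbinom(n, size = round(normal$raw_count), prob = 1 - alpha)
  })
  bins <- tumor$bins
  bin_profile(bins, mixed,
              sample_id = sprintf("%s_tf%02d", tumor$sample_id,
                                  round(100 * target_tf)),
              stage = "raw")
}

#' In-silico tumour-fraction dilution series
#'
#' Runs the full wGI pipeline (normalise, segment, cutoff, merge, LGA call,
#' wGI score, TF estimate) on the undiluted tumour and on each diluted
#' profile, and reports the stability floor: the lowest target tumour
#' fraction at which (and above which) the wGI status still equals the
#' undiluted status.
#'
#' @param tumor,normal Raw-stage [bin_profile()]s on the same bin set.
#' @param tumor_tf Tumour fraction of the undiluted tumour.
#' @param targets Target tumour fractions, sorted descending
#'   (e.g. `seq(0.6, 0.1, by = -0.1)`).
#' @param layout The `genome_layout` the bins were built from.
#' @param config A [wgi_config()].
#' @param seed Integer seed; each dilution level uses a sub-seed derived
#'   from it.
#' @return Data frame with one row per level (`target_tf`, `estimated_tf`,
#'   `lga_count`, `score`, `status`) plus attributes `undiluted_status`,
#'   `undiluted_score` and `stability_floor`.
#' @export
dilution_series <- function(tumor, normal, tumor_tf, targets, layout,
                            config = wgi_config(), seed = 1) {
  if (length(targets) == 0L)
    return(data.frame(target_tf = numeric(0), estimated_tf = numeric(0),
                      lga_count = integer(0), score = integer(0),
                      status = character(0)))
  if (is.unsorted(rev(targets), strictly = FALSE))
    stop2("targets must be sorted descending")
  base <- run_wgi(tumor, layout, config)
  rows <- vector("list", length(targets))
  for (k in seq_along(targets)) {
    rows[[k]] <- tryCatch({
      prof <- dilute_counts(tumor, normal, tumor_tf, targets[k],
                            seed = seed * 131L + k)
      frag <- run_wgi(prof, layout, config)
      data.frame(target_tf = targets[k], estimated_tf = frag$tf$fraction,
                 lga_count = frag$wgi$lga_count, score = frag$wgi$score,
                 status = frag$wgi$status, stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("dilution level ", targets[k], " failed: ", conditionMessage(e))
      data.frame(target_tf = targets[k], estimated_tf = NA_real_,
                 lga_count = NA_integer_, score = NA_integer_,
                 status = NA_character_, stringsAsFactors = FALSE)
    })
  }
  res <- do.call(rbind, rows)
  ok <- !is.na(res$status)
  floor_tf <- NA_real_
  for (k in seq_len(nrow(res))) {
    upper <- res$status[seq_len(k)]
    if (all(!is.na(upper)) && all(upper == base$wgi$status))
      floor_tf <- res$target_tf[k]
    else break
  }
  attr(res, "undiluted_status") <- base$wgi$status
  attr(res, "undiluted_score") <- base$wgi$score
  attr(res, "stability_floor") <- floor_tf
  res
}
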
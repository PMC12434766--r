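# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so simulation functions never leak global state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Round half away from zero, matching the reporting convention for
# percentages (92.85 -> 92.9), unlike base round()'s half-to-even.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Natural ordering for chromosome names: numeric first (with or without a
# "chr" prefix), then alphabetic, so layouts are order-invariant.
chrom_order <- function(x) {
  stripped <- sub("^chr", "", x)
  num <- suppressWarnings(as.numeric(stripped))
  order(is.na(num), num, stripped)
}

stop2 <- function(...) stop(..., call. = FALSE)
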
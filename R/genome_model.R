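# Genome layout (chromosomes, arm boundaries) and fixed-window bins.
# All coordinates are 0-based half-open, BED-style, everywhere in the package.

#' Load a chromosome-arm layout
#'
#' Builds a validated genome layout from a BED-like arm table with columns
#' `chromosome`, `start`, `end`, `arm` (values `p` or `q`). Chromosome length
#' is taken as the largest arm end. Row order is irrelevant; the layout is
#' sorted into natural chromosome order.
#'
#' @param arms A data frame with the four columns above, or a path to a
#'   tab-separated file with a header row.
#' @param build_label Free-text label describing the genome build.
#' @param autosomes_only Drop chromosomes named X/Y/M/MT (with or without a
#'   `chr` prefix). Instability scoring has an ambiguous copy-number baseline
#'   on sex chromosomes, so they are excluded by default.
#' @return An object of class `genome_layout`: a list with `chromosomes`
#'   (data frame of `chromosome`, `length`), `arms` (data frame of
#'   `chromosome`, `arm`, `start`, `end`) and `build_label`.
#' @export
#' @examples
#' arms <- data.frame(chromosome = "c1", start = c(0, 5e7),
#'                    end = c(5e7, 1e8), arm = c("p", "q"))
#' load_layout(arms)
load_layout <- function(arms, build_label = "unspecified", autosomes_only = TRUE) {
  if (is.character(arms) && length(arms) == 1L) {
    arms <- utils::read.delim(arms, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  }
  if (!is.data.frame(arms))
    stop2("'arms' must be a data frame or the path to a TSV file")
  need <- c("chromosome", "start", "end", "arm")
  if (!all(need %in% names(arms)))
    stop2("arm table must have columns: ", paste(need, collapse = ", "))
  arms <- arms[, need]
  for (i in seq_len(nrow(arms))) {
    row <- arms[i, ]
    s <- suppressWarnings(as.numeric(row$start))
    e <- suppressWarnings(as.numeric(row$end))
    if (is.na(s) || is.na(e) || s < 0 || e <= s || s != floor(s) || e != floor(e))
      stop2("malformed arm row ", i, ": start/end must be non-negative integers with start < end")
    if (!row$arm %in% c("p", "q"))
      stop2("malformed arm row ", i, ": arm must be 'p' or 'q'")
  }
  arms$start <- as.numeric(arms$start)
  arms$end <- as.numeric(arms$end)
  if (autosomes_only) {
    sex <- toupper(sub("^chr", "", arms$chromosome)) %in% c("X", "Y", "M", "MT")
    arms <- arms[!sex, , drop = FALSE]
  }
  if (nrow(arms) == 0L) stop2("no chromosomes left in arm table")
  arms <- arms[order(match(arms$chromosome,
                           arms$chromosome[chrom_order(arms$chromosome)]),
                     arms$start), , drop = FALSE]
  rownames(arms) <- NULL
  for (chr in unique(arms$chromosome)) {
    a <- arms[arms$chromosome == chr, , drop = FALSE]
    if (anyDuplicated(a$arm))
      stop2("chromosome ", chr, ": at most one p and one q arm allowed")
    if (nrow(a) == 2L) {
      a <- a[order(a$start), ]
      if (a$end[1] > a$start[2])
        stop2("chromosome ", chr, ": overlapping arms")
      if (a$arm[1] != "p" || a$arm[2] != "q")
        stop2("chromosome ", chr, ": p arm must precede q arm")
    }
  }
  chroms <- stats::aggregate(end ~ chromosome, data = arms, FUN = max)
  names(chroms) <- c("chromosome", "length")
  chroms <- chroms[match(unique(arms$chromosome), chroms$chromosome), ]
  rownames(chroms) <- NULL
  structure(list(chromosomes = chroms, arms = arms, build_label = build_label),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$arms), "arms, build:", x$build_label, "\n")
  invisible(x)
}

#' Construct fixed-width genomic bins
#'
#' Tiles each chromosome arm with consecutive windows of `bin_size` starting
#' at the arm start. Bins never straddle an arm boundary (so, structurally,
#' no copy-number segment can cross the centromere). A trailing partial
#' window shorter than half a bin is dropped; otherwise it is kept truncated.
#'
#' @param layout A `genome_layout`.
#' @param bin_size Window width in bp. The default (500 kb) is the enlarged
#'   window size that damps FFPE artefact signal relative to the 50 kb bins
#'   conventional for fresh-frozen sWGS.
#' @return A data frame of bins: `chromosome`, `start`, `end`, `arm`, `gc`,
#'   `mappability`, `usable`.
#' @export
make_bins <- function(layout, bin_size = 5e5) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0)
    stop2("bin_size must be a positive number")
  out <- vector("list", nrow(layout$arms))
  for (i in seq_len(nrow(layout$arms))) {
    a <- layout$arms[i, ]
    len <- a$end - a$start
    n_full <- floor(len / bin_size)
    rem <- len - n_full * bin_size
    starts <- a$start + bin_size * seq_len(n_full) - bin_size
    ends <- starts + bin_size
    if (rem >= bin_size / 2) {
      starts <- c(starts, a$start + n_full * bin_size)
      ends <- c(ends, a$end)
    }
    if (length(starts) == 0L) next
    out[[i]] <- data.frame(chromosome = a$chromosome, start = starts,
                           end = ends, arm = a$arm, stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(bins) <- NULL
  bins$gc <- NA_real_
  bins$mappability <- NA_real_
  bins$usable <- TRUE
  bins
}

#' Write a bin track to TSV
#'
#' @param bins Bin data frame from [make_bins()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bin_track <- function(bins, path) {
  utils::write.table(bins, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
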
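# Format writers and readers: bin-count TSV, SEG-style segment TSV,
# BED-like LGA tracks and JSON reports. Every writer/reader pair
# round-trips its domain type; JSON outputs echo the full configuration.

#' Write / read a bin-count table
#'
#' TSV with columns `chromosome`, `start`, `end`, `arm`, `gc`,
#' `mappability`, `usable`, `raw_count` (plus `corrected`, `log2_ratio`
#' once normalised). This is the alternative counts entry point to the
#' pipeline.
#'
#' @param profile A [bin_profile()].
#' @param path File path.
#' @return `write_bin_counts`: `path` invisibly. `read_bin_counts`: a
#'   `bin_profile` of the stage recorded in the file.
#' @export
write_bin_counts <- function(profile, path) {
  stopifnot(inherits(profile, "bin_profile"))
  df <- profile$bins
  df$raw_count <- profile$raw_count
  if (!is.null(profile$corrected)) df$corrected <- profile$corrected
  if (!is.null(profile$log2_ratio)) df$log2_ratio <- profile$log2_ratio
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_id=%s stage=%s", profile$sample_id,
                     profile$stage), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bin_counts
#' @export
read_bin_counts <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- regmatches(header, regexec("# sample_id=(\\S+) stage=(\\S+)", header))[[1]]
  if (length(meta) != 3L) stop2("not a bin-count file: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  bins <- df[, c("chromosome", "start", "end", "arm", "gc", "mappability", "usable")]
  bin_profile(bins, df$raw_count, sample_id = meta[2],
              corrected = df$corrected, log2_ratio = df$log2_ratio,
              stage = meta[3])
}

#' Write / read a SEG-style segment table
#'
#' Tab-separated segment table (`sample`, `chromosome`, `arm`, `start`,
#' `end`, `n_bins`, `bin_bp`, `mean_ratio`) with the merge state and CNA
#' cutoff recorded in comment headers so the pair round-trips.
#'
#' @param sp A [segment_profile()].
#' @param path File path.
#' @return `write_seg`: `path` invisibly. `read_seg`: a `segment_profile`.
#' @export
write_seg <- function(sp, path) {
  stopifnot(inherits(sp, "segment_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_id=%s merged=%s cutoff=%s", sp$sample_id,
                     sp$merged, format(sp$cna_cutoff_used, digits = 17)), con)
  df <- data.frame(sample = sp$sample_id, sp$segments, stringsAsFactors = FALSE)
  df$length <- NULL
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- regmatches(header, regexec(
    "# sample_id=(\\S+) merged=(\\S+) cutoff=(\\S+)", header))[[1]]
  if (length(meta) != 4L) stop2("not a SEG file written by write_seg: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  segment_profile(df[, c("chromosome", "arm", "start", "end", "n_bins",
                         "bin_bp", "mean_ratio")],
                  sample_id = meta[2], merged = as.logical(meta[3]),
                  cna_cutoff_used = as.numeric(meta[4]))
}

#' Write LGA calls as a BED-like track
#'
#' 0-based half-open intervals spanning the two flanking segments, with the
#' break position, gap and |delta| as extra columns.
#'
#' @param lgas Data frame from [call_lgas()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_lga_bed <- function(lgas, path) {
  df <- data.frame(chromosome = lgas$chromosome, start = lgas$left_start,
                   end = lgas$right_end, arm = lgas$arm,
                   break_position = lgas$break_position, gap = lgas$gap,
                   delta = lgas$delta)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Recursively strip S3 classes so jsonlite serialises plain lists.
as_plain <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    x <- unclass(x)
    attributes(x) <- list(names = names(x))
    return(lapply(x, as_plain))
  }
  if (is.numeric(x)) attributes(x) <- list(names = names(x))
  x
}

#' Write / read an HRD report (or wGI fragment) as JSON
#'
#' Deterministic JSON serialisation (no timestamps): identical inputs,
#' configuration and seed give byte-identical files. The full pipeline
#' configuration is echoed under `$config`.
#'
#' @param report An `hrd_report` or `wgi_fragment`.
#' @param path File path.
#' @return `write_report_json`: `path` invisibly. `read_report_json`: the
#'   parsed list (plain lists, not restored S3 objects).
#' @export
write_report_json <- function(report, path) {
  obj <- as_plain(report)
  obj$schema <- list(name = "wgiscore-report", version = "1")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read annotated variants from a TSV or VCF
#'
#' The TSV entry point expects the fully annotated columns `gene`, `vaf`,
#' `pop_freq`, `classification` (and optionally `variant_id`). The VCF
#' entry point (requires the vcfR package) reads VAF from the `VAF` or `AF`
#' INFO field and joins `pop_freq`/`classification` (and optionally `gene`)
#' from a sidecar TSV keyed by `variant_id` = `CHROM_POS_REF_ALT`.
#'
#' @param path Path to the annotated TSV or to a VCF.
#' @param sidecar Path to the sidecar TSV (VCF input only).
#' @return Data frame of variant records for [filter_variants()].
#' @export
read_variants <- function(path, sidecar = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop2("reading VCF requires the vcfR package; supply an annotated TSV instead")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    info_vaf <- suppressWarnings(as.numeric(vcfR::extract.info(v, "VAF")))
    if (all(is.na(info_vaf)))
      info_vaf <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
    out <- data.frame(
      variant_id = paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = "_"),
      gene = NA_character_, vaf = info_vaf, pop_freq = NA_real_,
      classification = NA_character_, stringsAsFactors = FALSE)
    if (!is.null(sidecar)) {
      sc <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
      if (!"variant_id" %in% names(sc))
        stop2("sidecar must have a variant_id column")
      idx <- match(out$variant_id, sc$variant_id)
      for (col in intersect(c("gene", "pop_freq", "classification"), names(sc)))
        out[[col]] <- sc[[col]][idx]
    }
    return(out)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "vaf", "pop_freq", "classification")
  if (!all(need %in% names(df)))
    stop2("annotated variant TSV needs columns: ", paste(need, collapse = ", "))
  df
}
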
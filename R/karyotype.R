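#' Read a depth track
#'
#' A depth track records sequencing read support per evaluated site
#' (`chrom pos count`) or per bin (`chrom start count`). Counts must be
#' non-negative; positions are sorted within chromosome.
#'
#' @param path TSV path with header `chrom pos count` (or
#'   `chrom start count` for binned tracks).
#' @return data.frame with columns `chrom`, `pos`, `count`.
#' @export
read_depth_track <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  names(d)[names(d) == "start"] <- "pos"
  depth_track(d)
}

#' @rdname read_depth_track
#' @param d data.frame with columns `chrom`, `pos` (or `start`), `count`.
#' @export
depth_track <- function(d) {
  stopifnot(all(c("chrom", "pos", "count") %in% names(d)))
  if (any(d$count < 0)) stop("counts must be non-negative")
  d$chrom <- normalize_chrom(d$chrom)
  d <- d[order(d$chrom, d$pos), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("depth_track", "data.frame")
  d
}

#' Normalized per-chromosome read counts
#'
#' Divides each chromosome's typical read count by the genome-wide
#' typical count over all evaluated sites. A disomic chromosome sits
#' near 1; a trisomic one is elevated toward 1.5 (before the elevation
#' itself drags the genome-wide statistic up). `robust = TRUE` uses
#' medians, which resist site-level mapping-rate outliers; the mean mode
#' satisfies the exact identity `sum(ratio * site_weight) == 1`.
#'
#' @param depth A [depth_track()] (or a data.frame with `chrom`, `pos`,
#'   `count`).
#' @param robust Use medians instead of means (default TRUE).
#' @param sites Optional `ancestry_blocks` (or any `chrom/left/right`
#'   table): only sites inside these intervals are evaluated —
#'   e.g. restrict to donor-like blocks so reference-vs-donor mapping
#'   differences cancel.
#' @return An object of class `karyotype_report`: data.frame with one
#'   row per chromosome (`chrom`, `n_sites`, `depth_stat`, `ratio`,
#'   `call` = NA), plus attributes `genome_stat` and `robust`.
#' @export
normalized_read_counts <- function(depth, robust = TRUE, sites = NULL) {
  if (!inherits(depth, "depth_track")) depth <- depth_track(depth)
  if (!is.null(sites)) {
    keep <- logical(nrow(depth))
    for (i in seq_len(nrow(sites))) {
      if ("label" %in% names(sites) && sites$label[i] != "DONOR_LIKE") next
      keep <- keep | (depth$chrom == normalize_chrom(sites$chrom[i]) &
                        depth$pos >= sites$left[i] &
                        depth$pos <= sites$right[i])
    }
    depth <- depth[keep, , drop = FALSE]
  }
  if (!nrow(depth)) stop("no evaluated sites")
  stat <- if (robust) stats::median else mean
  chroms <- unique(depth$chrom)
  per <- vapply(chroms, function(ch) stat(depth$count[depth$chrom == ch]),
                numeric(1))
  n <- vapply(chroms, function(ch) sum(depth$chrom == ch), numeric(1))
  genome <- stat(depth$count)
  if (genome <= 0) stop("genome-wide depth statistic is zero")
  rep <- data.frame(chrom = chroms, n_sites = n, depth_stat = per,
                    ratio = per / genome, call = NA_character_,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(rep, genome_stat = genome, robust = robust,
            class = c("karyotype_report", "data.frame"))
}

#' Call whole-chromosome ploidy from normalized read counts
#'
#' Thresholds sit between the expected disomic ratio (about 1) and the
#' expected trisomic (1.36-1.5 depending on how much of the genome the
#' extra chromosome contributes to the normalizer) or monosomic
#' (0.5-0.55) ratios.
#'
#' @param report A `karyotype_report` from [normalized_read_counts()].
#' @param tri_low Ratio at or above which a chromosome is called
#'   trisomic (default 1.2).
#' @param mono_high Ratio at or below which a chromosome is called
#'   monosomic (default 0.75).
#' @return The report with the `call` column filled in: `"trisomic"`,
#'   `"monosomic"`, `"disomic"`, or `"ambiguous"` for chromosomes with
#'   no evaluated sites.
#' @export
call_ploidy <- function(report, tri_low = 1.2, mono_high = 0.75) {
  stopifnot(inherits(report, "karyotype_report"), tri_low > mono_high)
  report$call <- ifelse(report$n_sites == 0, "ambiguous",
                 ifelse(report$ratio >= tri_low, "trisomic",
                 ifelse(report$ratio <= mono_high, "monosomic",
                        "disomic")))
  report
}

#' Write a karyotype report
#'
#' @param report A `karyotype_report`.
#' @param path Output path.
#' @param format `"json"` (`{chrom: {ratio, call}}`) or `"tsv"`.
#' @export
write_karyotype <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- stats::setNames(lapply(seq_len(nrow(report)), function(i)
      list(ratio = report$ratio[i], call = report$call[i])),
      report$chrom)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(as.data.frame(report), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
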
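#' Windowed SNP density along chromosomes
#'
#' Tiles (or slides over) each chromosome with fixed-width windows and
#' counts query SNPs per window. Donor introgressions in an otherwise
#' reference-like inbred genome show up as windows whose density is
#' orders of magnitude above background, which is what the downstream
#' segmentation thresholds on.
#'
#' @param t A [snp_table()].
#' @param chrom_lengths Named vector of chromosome lengths (bp); every
#'   chromosome present in `t` must be listed.
#' @param window_bp Window width in bp (default 100 kb).
#' @param step_bp Step between window starts (default 50 kb); equal to
#'   `window_bp` for non-overlapping tiling.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `snp_count` and `density` (SNPs per kb). Windows are
#'   clipped at chromosome ends.
#' @export
window_density <- function(t, chrom_lengths, window_bp = 1e5, step_bp = 5e4) {
  stopifnot(inherits(t, "snp_table"), window_bp >= step_bp, step_bp >= 1)
  names(chrom_lengths) <- normalize_chrom(names(chrom_lengths))
  missing_len <- setdiff(unique(t$variants$chrom), names(chrom_lengths))
  if (length(missing_len))
    stop("chromosome(s) in table but not in chrom_lengths: ",
         paste(missing_len, collapse = ", "))
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, max(0, len - 1), by = step_bp)
    starts <- starts[starts < len]
    ends <- pmin(starts + window_bp, len)
    p <- t$variants$pos[t$variants$chrom == ch]  # sorted by invariant
    # 1-based pos falls in [start, end) iff start < pos <= end
    cnt <- findInterval(ends, p) - findInterval(starts, p)
    data.frame(chrom = ch, start = starts, end = ends, snp_count = cnt,
               density = cnt / ((ends - starts) / 1000))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-window donor sharing against an accession panel
#'
#' For each window with at least `min_snps` query SNPs, computes for
#' every panel accession the fraction of the query's SNPs in that window
#' that the accession also carries (position + allele match). The
#' best-scoring accession is the candidate donor for that window;
#' windows with too few SNPs are flagged undefined.
#'
#' @param query A [snp_table()] for the stock under study.
#' @param panel An [accession_panel()] of candidate donors.
#' @param windows Output of [window_density()] on `query`.
#' @param min_snps Minimum query SNPs for a defined share (default 5).
#' @return `windows` with added columns `share_<accession>` per panel
#'   member, `best_donor` (NA when undefined) and `best_share`.
#' @export
donor_share <- function(query, panel, windows, min_snps = 5) {
  stopifnot(inherits(query, "snp_table"))
  if (!inherits(panel, "accession_panel")) panel <- accession_panel(panel)
  if (!length(panel)) stop("empty panel")
  qv <- query$variants
  qkey <- allele_key(qv)
  inpanel <- vapply(panel, function(acc) qkey %in% allele_key(acc$variants),
                    logical(nrow(qv)))
  if (nrow(qv) == 1) inpanel <- matrix(inpanel, nrow = 1)
  shares <- matrix(NA_real_, nrow(windows), length(panel),
                   dimnames = list(NULL, names(panel)))
  for (ch in unique(windows$chrom)) {
    qrows <- which(qv$chrom == ch)          # sorted by pos (invariant)
    if (!length(qrows)) next
    p <- qv$pos[qrows]
    cum <- rbind(0, apply(inpanel[qrows, , drop = FALSE], 2, cumsum))
    wrows <- which(windows$chrom == ch)
    lo <- findInterval(windows$start[wrows], p)
    hi <- findInterval(windows$end[wrows], p)
    n <- hi - lo
    ok <- n >= min_snps
    shares[wrows[ok], ] <- (cum[hi[ok] + 1, , drop = FALSE] -
                              cum[lo[ok] + 1, , drop = FALSE]) / n[ok]
  }
  colnames(shares) <- paste0("share_", names(panel))
  defined <- !is.na(shares[, 1])
  best_idx <- rep(NA_integer_, nrow(windows))
  best_idx[defined] <- apply(shares[defined, , drop = FALSE], 1, which.max)
  out <- cbind(windows, shares)
  out$best_donor <- ifelse(is.na(best_idx), NA_character_,
                           names(panel)[best_idx])
  out$best_share <- ifelse(is.na(best_idx), NA_real_,
                           shares[cbind(seq_len(nrow(shares)), best_idx)])
  out
}

#' Segment a genome into reference-like and donor-like ancestry blocks
#'
#' A window is called donor-like iff its SNP density is at least
#' `density_threshold` and its best-donor share at least
#' `share_threshold`; everything else (including windows with too few
#' SNPs to score — conservative toward no introgression) is
#' reference-like. Donor windows are merged into blocks, donor runs
#' shorter than `min_block_bp` are relabeled reference-like, and gaps up
#' to `merge_gap_bp` between same-donor blocks are closed. The
#' chromosome remainder is emitted as alternating REF_LIKE blocks.
#'
#' @param scored Output of [donor_share()] (windows with shares), or of
#'   [window_density()] when no panel is used (then any window passing
#'   the density threshold is donor-like with donor `NA`).
#' @param density_threshold Donor-calling density, SNPs/kb (default 1).
#' @param share_threshold Minimum best-donor share (default 0.8).
#' @param min_block_bp Minimum donor block length (default 200 kb).
#' @param merge_gap_bp Maximum gap closed between same-label donor
#'   blocks (default 20 kb).
#' @param chrom_lengths Named lengths used to emit the REF_LIKE
#'   remainder out to each chromosome end.
#' @return data.frame of class `ancestry_blocks`: columns `chrom`,
#'   `left`, `right` (1-based inclusive), `label` (`REF_LIKE` /
#'   `DONOR_LIKE`), `donor`, `n_snps`, `mean_share`. Blocks are sorted,
#'   non-overlapping and alternate in label within a chromosome.
#' @export
segment_ancestry <- function(scored, chrom_lengths,
                             density_threshold = 1, share_threshold = 0.8,
                             min_block_bp = 2e5, merge_gap_bp = 2e4) {
  stopifnot(density_threshold > 0,
            share_threshold > 0, share_threshold <= 1)
  names(chrom_lengths) <- normalize_chrom(names(chrom_lengths))
  has_share <- "best_share" %in% names(scored)
  donor_win <- scored$density >= density_threshold
  if (has_share)
    donor_win <- donor_win & !is.na(scored$best_share) &
      scored$best_share >= share_threshold
  res <- lapply(unique(scored$chrom), function(ch) {
    len <- chrom_lengths[[ch]]
    w <- scored[scored$chrom == ch, , drop = FALSE]
    dw <- w[donor_win[scored$chrom == ch], , drop = FALSE]
    db <- merge_windows(dw, gap = 0, has_share)
    db <- db[db$end - db$start >= min_block_bp, , drop = FALSE]  # short runs -> REF
    db <- close_gaps(db, merge_gap_bp)
    fill_reference(db, ch, len, w)
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  class(out) <- c("ancestry_blocks", "data.frame")
  out
}

# merge overlapping/adjacent donor windows (same donor) into [start,end) runs
merge_windows <- function(dw, gap, has_share) {
  if (!nrow(dw))
    return(data.frame(start = numeric(), end = numeric(),
                      donor = character(), n_snps = numeric(),
                      mean_share = numeric()))
  don <- if (has_share) dw$best_donor else rep(NA_character_, nrow(dw))
  ord <- order(dw$start)
  dw <- dw[ord, , drop = FALSE]
  don <- don[ord]
  runs <- list(); cur <- NULL
  for (i in seq_len(nrow(dw))) {
    if (!is.null(cur) && dw$start[i] <= cur$end + gap &&
        identical(don[i], cur$donor)) {
      cur$end <- max(cur$end, dw$end[i])
      cur$wins <- c(cur$wins, i)
    } else {
      if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
      cur <- list(start = dw$start[i], end = dw$end[i], donor = don[i],
                  wins = i)
    }
  }
  runs[[length(runs) + 1]] <- cur
  do.call(rbind, lapply(runs, function(r) data.frame(
    start = r$start, end = r$end, donor = r$donor,
    n_snps = sum(dw$snp_count[r$wins]),
    mean_share = if (has_share) mean(dw$best_share[r$wins]) else NA_real_)))
}

close_gaps <- function(db, merge_gap_bp) {
  if (nrow(db) < 2) return(db)
  keep <- db[1, , drop = FALSE]
  for (i in 2:nrow(db)) {
    j <- nrow(keep)
    if (db$start[i] - keep$end[j] <= merge_gap_bp &&
        identical(db$donor[i], keep$donor[j])) {
      keep$end[j] <- db$end[i]
      keep$n_snps[j] <- keep$n_snps[j] + db$n_snps[i]
      keep$mean_share[j] <- mean(c(keep$mean_share[j], db$mean_share[i]))
    } else keep <- rbind(keep, db[i, , drop = FALSE])
  }
  keep
}

# interleave REF_LIKE blocks around donor runs; coordinates flip to
# 1-based inclusive here
fill_reference <- function(db, ch, len, w) {
  blocks <- list()
  prev_end <- 0
  add <- function(left, right, label, donor, n_snps, mean_share)
    data.frame(chrom = ch, left = left, right = right, label = label,
               donor = donor, n_snps = n_snps, mean_share = mean_share,
               stringsAsFactors = FALSE)
  if (nrow(db)) db <- db[order(db$start), , drop = FALSE]
  for (i in seq_len(nrow(db))) {
    if (db$start[i] > prev_end)
      blocks[[length(blocks) + 1]] <-
        add(prev_end + 1, db$start[i], "REF_LIKE", NA_character_, NA_real_,
            NA_real_)
    blocks[[length(blocks) + 1]] <-
      add(db$start[i] + 1, db$end[i], "DONOR_LIKE", db$donor[i],
          db$n_snps[i], db$mean_share[i])
    prev_end <- db$end[i]
  }
  if (prev_end < len)
    blocks[[length(blocks) + 1]] <-
      add(prev_end + 1, len, "REF_LIKE", NA_character_, NA_real_, NA_real_)
  do.call(rbind, c(blocks, list(make.row.names = FALSE)))
}

#' Refine block borders to the outermost supporting SNPs
#'
#' Window segmentation localizes borders only to window resolution.
#' This step moves each donor-like border to the outermost query SNP in
#' the block that the donor also carries (position + allele), giving
#' marker-resolution borders; flanking reference-like blocks are
#' adjusted to stay non-overlapping. Donor blocks left with no
#' supporting SNP are removed with a warning.
#'
#' @param blocks Output of [segment_ancestry()].
#' @param query The query [snp_table()].
#' @param donor The donor accession's [snp_table()] (or an
#'   [accession_panel()]; each block then uses its own `donor` entry).
#' @return Refined `ancestry_blocks`.
#' @export
refine_breakpoints <- function(blocks, query, donor) {
  stopifnot(inherits(blocks, "data.frame"))
  qv <- query$variants
  donor_tables <- if (inherits(donor, "accession_panel")) donor else NULL
  donor_keys <- if (is.null(donor_tables))
    allele_key(donor$variants) else lapply(donor_tables, function(d)
      allele_key(d$variants))
  qkey <- allele_key(qv)
  out <- blocks
  drop <- logical(nrow(out))
  for (i in which(out$label == "DONOR_LIKE")) {
    keys <- if (is.null(donor_tables)) donor_keys else
      donor_keys[[out$donor[i]]]
    sup <- qv$chrom == out$chrom[i] & qv$pos >= out$left[i] &
      qv$pos <= out$right[i] & (qkey %in% keys)
    if (!any(sup)) { drop[i] <- TRUE; next }
    out$left[i] <- min(qv$pos[sup])
    out$right[i] <- max(qv$pos[sup])
    out$n_snps[i] <- sum(sup)
  }
  if (any(drop)) {
    warning(sum(drop), " donor block(s) removed: no supporting SNPs")
    out <- out[!drop, , drop = FALSE]
  }
  # re-abut the REF_LIKE neighbors
  for (ch in unique(out$chrom)) {
    idx <- which(out$chrom == ch)
    idx <- idx[order(out$left[idx])]
    for (k in seq_along(idx)[-1]) {
      i <- idx[k]; j <- idx[k - 1]
      if (out$label[i] == "REF_LIKE" && out$label[j] == "DONOR_LIKE")
        out$left[i] <- out$right[j] + 1
      if (out$label[i] == "DONOR_LIKE" && out$label[j] == "REF_LIKE")
        out$right[j] <- out$left[i] - 1
    }
  }
  out <- out[out$right >= out$left, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ancestry_blocks", "data.frame")
  out
}

#' Minimum historical crossover count from an ancestry mosaic
#'
#' Every transition between reference-like and donor-like ancestry in
#' the surviving genome witnesses at least one historical crossover, so
#' counting interior label transitions lower-bounds the number of
#' independent crossover events. Transitions within
#' `end_tolerance_bp` of a chromosome end are not counted: a donor block
#' that runs to the telomere needs no crossover on that side.
#'
#' @param blocks `ancestry_blocks` (only the DONOR_LIKE rows are used,
#'   so a bare donor-interval table with `chrom`, `left`, `right`
#'   columns also works).
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param end_tolerance_bp Distance from a chromosome end within which a
#'   border is treated as terminal (default 100 kb).
#' @return List of class `pedigree_bound`: `per_chrom_crossovers`
#'   (named vector over all chromosomes in `chrom_lengths`),
#'   `min_crossovers` (their sum).
#' @export
count_min_crossovers <- function(blocks, chrom_lengths,
                                 end_tolerance_bp = 1e5) {
  names(chrom_lengths) <- normalize_chrom(names(chrom_lengths))
  don <- if ("label" %in% names(blocks))
    blocks[blocks$label == "DONOR_LIKE", , drop = FALSE] else blocks
  per <- stats::setNames(integer(length(chrom_lengths)),
                         names(chrom_lengths))
  for (i in seq_len(nrow(don))) {
    ch <- normalize_chrom(don$chrom[i])
    len <- chrom_lengths[[ch]]
    if (is.null(len)) stop("no length for chromosome ", ch)
    if (don$left[i] > end_tolerance_bp + 1)
      per[ch] <- per[ch] + 1L
    if (don$right[i] < len - end_tolerance_bp)
      per[ch] <- per[ch] + 1L
  }
  structure(list(per_chrom_crossovers = per,
                 min_crossovers = sum(per)),
            class = "pedigree_bound")
}

#' Minimum number of meioses consistent with a crossover bound
#'
#' With an expected crossover rate of `rates[c]` per meiosis on
#' chromosome `c`, observing `k_c` independent crossovers requires at
#' least `ceiling(k_c / rates[c])` meioses; the genome-wide bound is the
#' maximum over chromosomes. Many observed crossovers on a single
#' chromosome therefore imply many generations between an outcross and
#' the present stock.
#'
#' @param bound A `pedigree_bound` from [count_min_crossovers()].
#' @param rates Named vector of expected crossovers per chromosome per
#'   meiosis (genetic length in Morgans x 2 is not assumed; supply the
#'   empirical rate).
#' @return The input with elements `crossover_rates` and `min_meioses`
#'   added.
#' @examples
#' b <- structure(list(per_chrom_crossovers = c(chr1 = 5),
#'                     min_crossovers = 5), class = "pedigree_bound")
#' min_meioses(b, c(chr1 = 1.7))$min_meioses  # ceiling(5/1.7) = 3
#' @export
min_meioses <- function(bound, rates) {
  stopifnot(inherits(bound, "pedigree_bound"))
  names(rates) <- normalize_chrom(names(rates))
  k <- bound$per_chrom_crossovers
  active <- names(k)[k > 0]
  missing_rate <- setdiff(active, names(rates))
  if (length(missing_rate))
    stop("no crossover rate for chromosome(s): ",
         paste(missing_rate, collapse = ", "))
  if (any(rates[active] <= 0)) stop("rates must be positive")
  bound$crossover_rates <- rates
  bound$min_meioses <- if (!length(active)) 0L else
    as.integer(ceiling(max(k[active] / rates[active])))
  bound
}

#' @exportS3Method base::print
print.pedigree_bound <- function(x, ...) {
  cat("pedigree_bound: >=", x$min_crossovers, "crossovers")
  if (!is.null(x$min_meioses)) cat(", >=", x$min_meioses, "meioses")
  cat("\n")
  print(x$per_chrom_crossovers)
  invisible(x)
}

#' Write ancestry blocks to disk
#'
#' `format = "tsv"` writes the 1-based inclusive block table
#' (`chrom left right label donor n_snps mean_share`), read back by
#' [read_blocks()]. `format = "bed"` writes BED6 with 0-based half-open
#' coordinates, name = donor (`.` for reference-like) and
#' score = `floor(1000 * mean_share)`.
#'
#' @param blocks `ancestry_blocks`.
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @export
write_blocks <- function(blocks, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- blocks
    for (cc in c("left", "right"))
      out[[cc]] <- format(out[[cc]], scientific = FALSE, trim = TRUE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  } else {
    score <- ifelse(is.na(blocks$mean_share), 0,
                    floor(1000 * blocks$mean_share))
    bed <- data.frame(chrom = blocks$chrom,
                      start = format(blocks$left - 1, scientific = FALSE,
                                     trim = TRUE),
                      end = format(blocks$right, scientific = FALSE,
                                   trim = TRUE),
                      name = ifelse(is.na(blocks$donor), ".", blocks$donor),
                      score = score, strand = ".")
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_blocks
#' @export
read_blocks <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  class(out) <- c("ancestry_blocks", "data.frame")
  out
}

#' One-call ancestry painting pipeline
#'
#' Convenience wrapper running [window_density()], [donor_share()],
#' [segment_ancestry()] and [refine_breakpoints()] with shared defaults.
#'
#' @inheritParams window_density
#' @inheritParams donor_share
#' @inheritParams segment_ancestry
#' @param refine Refine borders to outermost supporting SNPs?
#' @return `ancestry_blocks`.
#' @export
paint_ancestry <- function(query, panel, chrom_lengths,
                           window_bp = 1e5, step_bp = 5e4, min_snps = 5,
                           density_threshold = 1, share_threshold = 0.8,
                           min_block_bp = 2e5, merge_gap_bp = 2e4,
                           refine = TRUE) {
  w <- window_density(query, chrom_lengths, window_bp, step_bp)
  s <- donor_share(query, panel, w, min_snps = min_snps)
  b <- segment_ancestry(s, chrom_lengths, density_threshold,
                        share_threshold, min_block_bp, merge_gap_bp)
  if (refine) b <- refine_breakpoints(b, query, panel)
  b
}
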
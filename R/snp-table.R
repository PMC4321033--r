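#' Construct a per-sample SNP table
#'
#' A `snp_table` holds the homozygous variant calls of one inbred sample
#' against a common reference genome: one record per site, sorted by
#' (chrom, pos), 1-based coordinates. It is the unit of all set algebra,
#' density analysis and ancestry painting in this package.
#'
#' @param variants A data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   and optionally `support` (non-negative read count). `pos` must be a
#'   positive integer; `ref` and `alt` single bases over A/C/G/T for SNPs.
#' @param sample_name Sample identifier string.
#' @param normalize Normalize chromosome names via [normalize_chrom()]?
#' @param keep_indels Keep records whose alleles are not both single
#'   bases? Indels are tolerated for I/O but excluded from density and
#'   painting computations, which are defined on SNPs.
#' @return An object of class `snp_table`: a list with elements
#'   `sample_name` and `variants` (the validated, sorted data.frame).
#' @examples
#' snp_table(data.frame(chrom = "chr1", pos = c(100, 200),
#'                      ref = c("A", "G"), alt = c("T", "C")), "toy")
#' @export
snp_table <- function(variants, sample_name = "sample", normalize = TRUE,
                      keep_indels = FALSE) {
  stopifnot(is.data.frame(variants))
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("variants lacks column(s): ", paste(miss, collapse = ", "))
  v <- data.frame(chrom = as.character(variants$chrom),
                  pos = as.numeric(variants$pos),
                  ref = toupper(as.character(variants$ref)),
                  alt = toupper(as.character(variants$alt)),
                  support = if ("support" %in% names(variants))
                    as.numeric(variants$support) else
                      rep(NA_real_, nrow(variants)),
                  stringsAsFactors = FALSE)
  if (normalize) v$chrom <- normalize_chrom(v$chrom)
  if (nrow(v)) {
    if (any(!is.finite(v$pos)) || any(v$pos < 1) || any(v$pos != floor(v$pos)))
      stop("pos must be positive integers (1-based)")
    if (any(v$ref == v$alt))
      stop("ref and alt alleles must differ")
    is_snp <- grepl("^[ACGT]$", v$ref) & grepl("^[ACGT]$", v$alt)
    if (!keep_indels && any(!is_snp)) {
      message(sum(!is_snp), " non-SNP record(s) dropped")
      v <- v[is_snp, , drop = FALSE]
    }
    if (!all(grepl("^[ACGT]+$", v$ref) & grepl("^[ACGT]+$", v$alt)))
      stop("alleles must be non-empty strings over A/C/G/T")
    v <- v[order(v$chrom, v$pos), , drop = FALSE]
    dup <- duplicated(v[c("chrom", "pos")])
    if (any(dup))
      stop("duplicate (chrom, pos) record(s), e.g. ",
           v$chrom[dup][1], ":", v$pos[dup][1])
    rownames(v) <- NULL
  }
  structure(list(sample_name = as.character(sample_name), variants = v),
            class = "snp_table")
}

#' @exportS3Method base::print
print.snp_table <- function(x, ...) {
  cat("snp_table '", x$sample_name, "': ", nrow(x$variants),
      " variants on ", length(unique(x$variants$chrom)),
      " chromosome(s)\n", sep = "")
  if (nrow(x$variants)) print(utils::head(x$variants, 6))
  invisible(x)
}

#' @export
length.snp_table <- function(x) nrow(x$variants)

#' @export
as.data.frame.snp_table <- function(x, ...) x$variants

site_key <- function(v) paste(v$chrom, v$pos, sep = ":")
allele_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Read a SNP table from disk
#'
#' Two dialects are supported. `"tsv"` is a 4/5-column tab-separated file
#' with header `chrom pos ref alt [support]`. `"vcf-min"` is a minimal
#' VCF v4.x subset: only CHROM, POS, REF, ALT (and DP, used as `support`)
#' are honored; a multi-allelic record resolves to the allele its
#' (homozygous) genotype calls, since an inbred sample carries exactly
#' one alternate allele per site; heterozygous genotype calls are
#' dropped with a warning because the pipeline models homozygous inbred
#' calls.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"vcf-min"`; `"auto"` decides from the file
#'   extension and first line.
#' @param sample_name Sample name; defaults to the file's base name.
#' @inheritParams snp_table
#' @return A [snp_table()].
#' @export
read_snp_table <- function(path, dialect = c("auto", "tsv", "vcf-min"),
                           sample_name = NULL, normalize = TRUE,
                           keep_indels = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_name))
    sample_name <- sub("\\.(vcf|tsv|txt)$", "", basename(path))
  if (dialect == "auto") {
    first <- readLines(path, n = 1L)
    dialect <- if (grepl("^##fileformat=VCF", first) ||
                   grepl("\\.vcf$", path)) "vcf-min" else "tsv"
  }
  v <- if (dialect == "vcf-min") read_vcf_min(path) else read_snp_tsv(path)
  snp_table(v, sample_name, normalize = normalize, keep_indels = keep_indels)
}

read_snp_tsv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file with no header: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!all(c("chrom", "pos", "ref", "alt") %in% header))
    stop("TSV header must contain chrom, pos, ref, alt; got: ", lines[[1]])
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) {
    out <- data.frame(chrom = character(), pos = numeric(),
                      ref = character(), alt = character())
    return(out)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  # a trailing empty support field is dropped by strsplit; restore it
  if ("support" %in% header)
    parts <- lapply(parts, function(p)
      if (length(p) == length(header) - 1) c(p, NA_character_) else p)
  bad <- which(lengths(parts) != length(header))
  if (length(bad))
    stop("parse error at line ", bad[1] + 1L, " of ", path,
         ": expected ", length(header), " fields")
  m <- do.call(rbind, parts)
  colnames(m) <- header
  out <- data.frame(chrom = m[, "chrom"],
                    pos = suppressWarnings(as.numeric(m[, "pos"])),
                    ref = m[, "ref"], alt = m[, "alt"],
                    stringsAsFactors = FALSE)
  if ("support" %in% header)
    out$support <- suppressWarnings(as.numeric(m[, "support"]))
  if (any(is.na(out$pos)))
    stop("parse error at line ", which(is.na(out$pos))[1] + 1L, " of ",
         path, ": non-numeric pos")
  out
}

read_vcf_min <- function(path) {
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0)
    return(data.frame(chrom = character(), pos = numeric(),
                      ref = character(), alt = character()))
  dp <- tryCatch(suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, "DP"))), error = function(e) NULL)
  keep <- rep(TRUE, n)
  called <- rep(NA_integer_, n)  # 1-based alt index from a hom GT
  # drop heterozygous genotype calls when a GT column is present
  gt <- tryCatch(vcfR::extract.gt(vcf, element = "GT"),
                 error = function(e) NULL)
  if (!is.null(gt) && ncol(gt) >= 1) {
    g <- gsub("\\|", "/", gt[, 1])
    a <- sub("/.*", "", g); b <- sub(".*/", "", g)
    het <- !is.na(g) & a != b
    if (any(het)) {
      warning(sum(het), " heterozygous record(s) rejected (pipeline ",
              "models homozygous inbred calls)")
      keep <- keep & !het
    }
    called[!het & !is.na(g)] <- suppressWarnings(
      as.integer(a[!het & !is.na(g)]))
  }
  recs <- lapply(which(keep), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    # multi-allelic records resolve to the single called allele: a
    # homozygous inbred sample carries exactly one alternate allele
    alt <- if (length(alts) > 1 && !is.na(called[i]) && called[i] >= 1 &&
               called[i] <= length(alts)) alts[called[i]] else alts[1]
    data.frame(chrom = fix[i, "CHROM"],
               pos = as.numeric(fix[i, "POS"]),
               ref = fix[i, "REF"], alt = alt,
               support = if (is.null(dp)) NA_real_ else dp[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame(chrom = character(), pos = numeric(),
                                      ref = character(), alt = character())
  out
}

#' Write a SNP table as TSV
#'
#' Writes the 5-column dialect read back losslessly by
#' [read_snp_table()]: `chrom pos ref alt support` (support blank when
#' unknown).
#'
#' @param t A [snp_table()].
#' @param path Output file path.
#' @export
write_snp_table <- function(t, path) {
  stopifnot(inherits(t, "snp_table"))
  v <- t$variants
  v$pos <- format(v$pos, scientific = FALSE, trim = TRUE)
  utils::write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Set algebra on SNP tables
#'
#' `intersect_snps()` returns the variants of `a` also present in `b`;
#' `subtract_snps()` the variants of `a` absent from `b`. With
#' `match_mode = "position"` two records match when they share
#' (chrom, pos); with `"position+allele"` the ref and alt alleles must
#' also agree. Results always carry `a`'s allele records, so
#' `intersect` and `subtract` partition `a` exactly.
#'
#' @param a,b [snp_table()] objects on the same reference.
#' @param match_mode `"position"` or `"position+allele"`.
#' @return A [snp_table()] named after `a`.
#' @examples
#' a <- snp_table(data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "T"))
#' b <- snp_table(data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "G"))
#' length(intersect_snps(a, b, "position"))          # 1
#' length(intersect_snps(a, b, "position+allele"))   # 0
#' @export
intersect_snps <- function(a, b, match_mode = c("position", "position+allele")) {
  match_mode <- match.arg(match_mode)
  stopifnot(inherits(a, "snp_table"), inherits(b, "snp_table"))
  keyfun <- if (match_mode == "position") site_key else allele_key
  keep <- keyfun(a$variants) %in% keyfun(b$variants)
  snp_table(a$variants[keep, , drop = FALSE], a$sample_name,
            normalize = FALSE, keep_indels = TRUE)
}

#' @rdname intersect_snps
#' @export
subtract_snps <- function(a, b, match_mode = c("position", "position+allele")) {
  match_mode <- match.arg(match_mode)
  stopifnot(inherits(a, "snp_table"), inherits(b, "snp_table"))
  keyfun <- if (match_mode == "position") site_key else allele_key
  keep <- !(keyfun(a$variants) %in% keyfun(b$variants))
  snp_table(a$variants[keep, , drop = FALSE], a$sample_name,
            normalize = FALSE, keep_indels = TRUE)
}

#' Inter-SNP distance series along one chromosome
#'
#' Distance in bp from each SNP to the previous one, the classic display
#' for spotting dense (divergent-haplotype) versus sparse
#' (reference-like) regions along a chromosome.
#'
#' @param t A [snp_table()].
#' @param chrom Chromosome name (normalized).
#' @return data.frame with columns `pos` (position of the right-hand SNP
#'   of each pair) and `distance` (bp, >= 1); zero rows when the
#'   chromosome has fewer than 2 SNPs.
#' @examples
#' t <- snp_table(data.frame(chrom = "chr1", pos = c(100, 150, 400),
#'                           ref = "A", alt = "T"))
#' inter_snp_distances(t, "chr1")$distance  # 50 250
#' @export
inter_snp_distances <- function(t, chrom) {
  stopifnot(inherits(t, "snp_table"))
  p <- t$variants$pos[t$variants$chrom == normalize_chrom(chrom)]
  if (length(p) < 2)
    return(data.frame(pos = numeric(), distance = numeric()))
  data.frame(pos = p[-1], distance = diff(p))
}

#' Per-chromosome SNP counts
#'
#' @param t A [snp_table()].
#' @param chroms Optional chromosome names to report (zero-filled);
#'   defaults to the chromosomes observed in the table.
#' @return Named integer vector of counts; sums to `length(t)` when
#'   `chroms` covers all observed chromosomes.
#' @export
snp_counts_by_chromosome <- function(t, chroms = NULL) {
  stopifnot(inherits(t, "snp_table"))
  tab <- table(t$variants$chrom)
  if (is.null(chroms)) chroms <- names(tab)
  out <- stats::setNames(integer(length(chroms)), chroms)
  hit <- intersect(names(tab), chroms)
  out[hit] <- as.integer(tab[hit])
  out
}

#' An accession panel: named collection of SNP tables
#'
#' @param ... [snp_table()] objects (or a single list of them), all on
#'   the same reference coordinate system. Names default to each table's
#'   `sample_name` and must be unique.
#' @return An object of class `accession_panel` (named list of tables).
#' @export
accession_panel <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && is.list(tabs[[1]]) &&
      !inherits(tabs[[1]], "snp_table"))
    tabs <- tabs[[1]]
  if (!length(tabs)) stop("empty panel")
  stopifnot(all(vapply(tabs, inherits, TRUE, "snp_table")))
  nm <- names(tabs)
  if (is.null(nm)) nm <- rep("", length(tabs))
  nm[nm == ""] <- vapply(tabs[nm == ""], `[[`, "", "sample_name")
  if (anyDuplicated(nm)) stop("accession names must be unique")
  names(tabs) <- nm
  structure(tabs, class = "accession_panel")
}

#' @exportS3Method base::print
print.accession_panel <- function(x, ...) {
  cat("accession_panel of", length(x), "table(s):\n")
  for (nm in names(x))
    cat("  ", nm, ": ", nrow(x[[nm]]$variants), " variants\n", sep = "")
  invisible(x)
}
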
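#' Normalize chromosome names to a canonical form
#'
#' Mixed inputs ("Chr1", "chr1", "1", "CHR1") are mapped onto a single
#' canonical spelling so that tables from different callers can be
#' intersected. The default canonical form is `"chr<n>"`.
#'
#' @param x Character vector of chromosome names.
#' @param aliases Optional named character vector mapping raw names to
#'   canonical ones; entries here take precedence over the built-in rule.
#' @return Character vector of canonical chromosome names.
#' @examples
#' normalize_chrom(c("Chr1", "1", "chr1"))
#' @export
normalize_chrom <- function(x, aliases = NULL) {
  x <- as.character(x)
  out <- tolower(x)
  # bare numerals or roman-free labels get the chr prefix
  bare <- grepl("^[0-9ivx]+$", out)
  out[bare] <- paste0("chr", out[bare])
  if (!is.null(aliases)) {
    hit <- match(x, names(aliases))
    out[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  out
}

#' Approximate Arabidopsis thaliana nuclear chromosome lengths
#'
#' Named vector of base-pair lengths for the five nuclear chromosomes,
#' matching the coordinate system of the standard Col-0 reference assembly.
#' Bundled as a convenient default for windowing and crossover counting;
#' supply your own lengths for other assemblies or species.
#'
#' @return Named numeric vector (bp), names `chr1`..`chr5`.
#' @examples
#' arabidopsis_chrom_lengths()
#' @export
arabidopsis_chrom_lengths <- function() {
  c(chr1 = 30427671, chr2 = 19698289, chr3 = 23459830,
    chr4 = 18585056, chr5 = 26975502)
}
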
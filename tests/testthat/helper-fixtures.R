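# Shared fixtures and independent oracles for the suite.

# Published donor-introgression intervals for the CS3227 stock
# (1-based bp borders on the Col-0 reference): three blocks on chr1,
# one on chr2 touching the start, two on chr3 separated by 14,394 bp,
# one on chr4 touching the start. Used as planted truth throughout.
cs3227_intervals <- function() {
  data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr3", "chr3", "chr4"),
    left = c(10180611, 21543989, 28423595, 1, 1732545, 4289162, 1),
    right = c(19875136, 22196062, 30427017, 302692, 4274768, 4622728,
              6215838))
}

# brute-force set-algebra oracle: O(n*m) nested scan, no sorting tricks
brute_match <- function(a, b, mode) {
  av <- a$variants; bv <- b$variants
  hit <- logical(nrow(av))
  for (i in seq_len(nrow(av))) {
    for (j in seq_len(nrow(bv))) {
      same_site <- av$chrom[i] == bv$chrom[j] && av$pos[i] == bv$pos[j]
      if (same_site &&
          (mode == "position" ||
           (av$ref[i] == bv$ref[j] && av$alt[i] == bv$alt[j]))) {
        hit[i] <- TRUE
        break
      }
    }
  }
  hit
}

brute_intersect <- function(a, b, mode) {
  snp_table(a$variants[brute_match(a, b, mode), , drop = FALSE],
            a$sample_name, normalize = FALSE)
}

brute_subtract <- function(a, b, mode) {
  snp_table(a$variants[!brute_match(a, b, mode), , drop = FALSE],
            a$sample_name, normalize = FALSE)
}

random_snp_table <- function(n, chroms = c("chr1", "chr2"),
                             max_pos = 1e5, name = "rnd") {
  bases <- c("A", "C", "G", "T")
  pos_pool <- sample.int(max_pos, n)
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  snp_table(data.frame(chrom = sample(chroms, n, replace = TRUE),
                       pos = pos_pool, ref = ref, alt = unname(alt)),
            name, normalize = FALSE)
}

# small two-chromosome world used by several painting tests
toy_lengths <- function() c(chr1 = 5e6, chr2 = 4e6)
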
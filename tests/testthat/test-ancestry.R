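test_that("window density tiles chromosomes and counts every SNP once", {
  lens <- c(chr1 = 1e6)
  empty <- snp_table(data.frame(chrom = character(), pos = numeric(),
                                ref = character(), alt = character()))
  w <- window_density(empty, lens, 1e5, 1e5)
  expect_equal(nrow(w), 10)
  expect_true(all(w$snp_count == 0))
  expect_equal(w$density, w$snp_count / ((w$end - w$start) / 1000))

  t <- snp_table(data.frame(chrom = "chr1",
                            pos = seq(1000, 91000, by = 10000),
                            ref = "A", alt = "T"))
  w <- window_density(t, lens, 1e5, 1e5)
  expect_equal(w$snp_count, c(10, rep(0, 9)))
  # tiling counts each SNP exactly once
  expect_equal(sum(w$snp_count), 10)

  # sliding windows count each interior SNP window/step times
  w2 <- window_density(t, lens, 1e5, 5e4)
  expect_equal(sum(w2$snp_count[w2$start == 0]), 10)
  expect_error(window_density(t, c(chr9 = 1e6), 1e5, 1e5),
               "chrom_lengths")
})

test_that("two-density genome gives bimodal window densities at the
           planted rates", {
  set.seed(21)
  lens <- c(chr1 = 4e6)
  # donor block [1.0, 2.5] Mb at 6 SNPs/kb; background 0.013 SNPs/kb
  donor_pos <- sort(sample(1000001:2500000, rpois(1, 6 * 1500)))
  bg_pos <- sort(sample(c(1:1000000, 2500001:4000000),
                        rpois(1, 0.013 * 2500)))
  t <- snp_table(data.frame(chrom = "chr1",
                            pos = sort(unique(c(donor_pos, bg_pos))),
                            ref = "A", alt = "T"))
  w <- window_density(t, lens, 1e5, 1e5)
  inside <- w$start >= 1e6 & w$end <= 2.5e6
  # Poisson rate 600/window inside, 1.3/window outside; 4-sigma bands
  expect_true(all(abs(w$snp_count[inside] - 600) <= 4 * sqrt(600)))
  expect_true(all(w$snp_count[!inside] <= 1.3 + 4 * sqrt(1.3) + 1))
  expect_gt(min(w$density[inside]), 1)
  expect_lt(max(w$density[!inside]), 1)
})

test_that("donor share identifies the donor and flags sparse windows", {
  set.seed(31)
  lens <- toy_lengths()
  panel <- simulate_founders(
    data.frame(name = c("donor", "decoy", "bg"),
               density = c(6, 6, 0.013)), lens, seed = 5)
  genome <- mosaic_from_blocks(
    data.frame(chrom = "chr1", left = 1e6, right = 3e6), lens,
    donor = "donor", background = "bg")
  q <- emit_snp_table(genome, panel, seed = 6)$table
  w <- window_density(q, lens, 1e5, 1e5)
  s <- donor_share(q, panel, w)
  inblock <- s$chrom == "chr1" & s$start >= 1e6 & s$end <= 3e6
  expect_true(all(s$best_donor[inblock] == "donor"))
  expect_true(all(s$share_donor[inblock] > 0.95))
  expect_true(all(s$share_decoy[inblock] < 0.2))
  # query scored against itself shares 1.0 wherever defined
  self <- donor_share(q, accession_panel(q), w)
  defined <- !is.na(self$best_share)
  expect_true(all(self$best_share[defined] == 1))
  # windows with too few SNPs are flagged undefined
  expect_true(all(is.na(self$best_share[self$snp_count < 5])))
  expect_error(donor_share(q, list(), w), "empty panel")
})

test_that("segmentation produces alternating blocks with the planted
           structure", {
  set.seed(41)
  lens <- toy_lengths()
  panel <- simulate_founders(
    data.frame(name = c("donor", "bg"), density = c(6, 0.013)),
    lens, seed = 15)
  # all background -> one REF_LIKE block per chromosome
  g0 <- mosaic_from_blocks(
    data.frame(chrom = character(), left = numeric(), right = numeric()),
    lens, donor = "donor", background = "bg")
  q0 <- emit_snp_table(g0, panel, seed = 16)$table
  b0 <- paint_ancestry(q0, panel, lens, refine = FALSE)
  expect_equal(nrow(b0), 2)
  expect_true(all(b0$label == "REF_LIKE"))

  # one interior donor block -> REF, DONOR, REF on that chromosome
  g1 <- mosaic_from_blocks(
    data.frame(chrom = "chr1", left = 2e6, right = 3e6), lens,
    donor = "donor", background = "bg")
  q1 <- emit_snp_table(g1, panel, seed = 17)$table
  b1 <- paint_ancestry(q1, panel, lens, refine = FALSE)
  chr1b <- b1[b1$chrom == "chr1", ]
  expect_equal(chr1b$label, c("REF_LIKE", "DONOR_LIKE", "REF_LIKE"))
  # blocks are sorted, non-overlapping, alternate, cover the chromosome
  expect_true(all(diff(chr1b$left) > 0))
  expect_true(all(chr1b$left[-1] == chr1b$right[-nrow(chr1b)] + 1))
})

test_that("the seven published donor intervals are recovered; the chr3
           pair merges iff the gap setting allows", {
  lens <- arabidopsis_chrom_lengths()
  iv <- cs3227_intervals()
  panel <- simulate_founders(
    data.frame(name = c("est", "bg"), density = c(6, 0.013)),
    lens, seed = 23)
  genome <- mosaic_from_blocks(iv, lens, donor = "est",
                               background = "bg")
  q <- emit_snp_table(genome, panel, seed = 24)$table

  # 10 kb windows resolve the 14,394 bp gap between the chr3 pair
  # (realized gap is one background window at that resolution);
  # merge_gap 20 kb closes it (6 blocks), 5 kb keeps it open (7)
  merged <- paint_ancestry(q, panel, lens, window_bp = 1e4,
                           step_bp = 1e4, merge_gap_bp = 2e4)
  expect_equal(sum(merged$label == "DONOR_LIKE"), 6)
  unmerged <- paint_ancestry(q, panel, lens, window_bp = 1e4,
                             step_bp = 1e4, merge_gap_bp = 5e3)
  expect_equal(sum(unmerged$label == "DONOR_LIKE"), 7)

  # each planted interval is matched by a recovered block within 100 kb
  don <- unmerged[unmerged$label == "DONOR_LIKE", ]
  for (i in seq_len(nrow(iv))) {
    hit <- don$chrom == iv$chrom[i] &
      abs(don$left - iv$left[i]) <= 1e5 &
      abs(don$right - iv$right[i]) <= 1e5
    expect_true(any(hit), info = paste("interval", i))
  }
})

test_that("breakpoint refinement lands on the outermost supporting SNPs", {
  lens <- c(chr1 = 5e6)
  # donor SNPs every 10 kb in [1e6, 2e6]; window segmentation border
  # will overshoot, refinement must pull it back to the SNPs
  dpos <- seq(1e6, 2e6, by = 1e4)
  donor <- snp_table(data.frame(chrom = "chr1", pos = dpos, ref = "A",
                                alt = "T"), "donor", normalize = FALSE)
  blocks <- data.frame(chrom = "chr1", left = c(1, 9e5, 2.1e6),
                       right = c(9e5 - 1, 2.1e6 - 1, 5e6),
                       label = c("REF_LIKE", "DONOR_LIKE", "REF_LIKE"),
                       donor = c(NA, "donor", NA),
                       n_snps = NA_real_, mean_share = NA_real_)
  class(blocks) <- c("ancestry_blocks", "data.frame")
  ref <- refine_breakpoints(blocks, donor, donor)
  don <- ref[ref$label == "DONOR_LIKE", ]
  expect_equal(don$left, 1e6)
  expect_equal(don$right, 2e6)
  # neighbors re-abutted
  expect_equal(ref$right[1], 1e6 - 1)
  expect_equal(ref$left[3], 2e6 + 1)
  # a block with no supporting SNP is removed with a warning
  blocks2 <- blocks
  blocks2$left[2] <- 3e6; blocks2$right[2] <- 4e6
  expect_warning(ref2 <- refine_breakpoints(blocks2, donor, donor),
                 "no supporting")
  expect_false(any(ref2$label == "DONOR_LIKE"))
  # refinement is a fixed point when borders already sit on SNPs
  expect_equal(refine_breakpoints(ref, donor, donor)[
    ref$label == "DONOR_LIKE", c("left", "right")],
    don[, c("left", "right")])
})

test_that("crossover counting follows the end-tolerance rule on the
           published intervals", {
  lens <- arabidopsis_chrom_lengths()
  iv <- cs3227_intervals()
  # unmerged: 11 interior borders (chr2/chr4 left at start, chr1 third
  # block right within 100 kb of the chromosome end are excluded)
  b_un <- count_min_crossovers(iv, lens, end_tolerance_bp = 1e5)
  expect_equal(b_un$min_crossovers, 11)
  expect_equal(unname(b_un$per_chrom_crossovers["chr1"]), 5)
  # merged chr3 pair: 9
  ivm <- iv[-6, ]
  ivm$right[5] <- iv$right[6]
  b_m <- count_min_crossovers(ivm, lens, end_tolerance_bp = 1e5)
  expect_equal(b_m$min_crossovers, 9)
  expect_true(b_un$min_crossovers >= 8 && b_m$min_crossovers >= 8)

  # single whole-chromosome block -> 0; one interior block -> 2
  whole <- data.frame(chrom = "chr1", left = 1, right = lens[["chr1"]])
  expect_equal(count_min_crossovers(whole, lens)$min_crossovers, 0)
  inner <- data.frame(chrom = "chr1", left = 2e6, right = 3e6)
  expect_equal(count_min_crossovers(inner, lens)$min_crossovers, 2)
})

test_that("minimum meioses is the ceiling of the worst chromosome", {
  lens <- arabidopsis_chrom_lengths()
  rates <- setNames(rep(1.7, 5), names(lens))
  mk <- function(k) structure(
    list(per_chrom_crossovers = c(chr1 = k, chr2 = 0, chr3 = 0,
                                  chr4 = 0, chr5 = 0),
         min_crossovers = k), class = "pedigree_bound")
  expect_equal(min_meioses(mk(0), rates)$min_meioses, 0)
  expect_equal(min_meioses(mk(5), rates)$min_meioses, 3)   # ceil(2.94)
  expect_equal(min_meioses(mk(8), rates)$min_meioses, 5)   # ceil(4.71)
  expect_error(min_meioses(mk(5), c(chr2 = 1.7)), "no crossover rate")
})

test_that("block output formats convert coordinates and round-trip", {
  blocks <- data.frame(chrom = "chr1", left = 10180611, right = 19875136,
                       label = "DONOR_LIKE", donor = "est",
                       n_snps = 100, mean_share = 0.9876)
  class(blocks) <- c("ancestry_blocks", "data.frame")
  bed <- tempfile(fileext = ".bed")
  write_blocks(blocks, bed, "bed")
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(as.numeric(fields[2]), 10180610)  # 0-based half-open
  expect_equal(as.numeric(fields[3]), 19875136)
  expect_equal(fields[4], "est")
  expect_equal(as.numeric(fields[5]), floor(1000 * 0.9876))

  tsv <- tempfile(fileext = ".tsv")
  write_blocks(blocks, tsv, "tsv")
  back <- read_blocks(tsv)
  expect_equal(back$left, blocks$left)
  expect_equal(back$right, blocks$right)
  expect_equal(back$label, blocks$label)
  expect_equal(back$donor, blocks$donor)

  empty <- blocks[0, ]
  write_blocks(empty, tsv, "tsv")
  expect_equal(length(readLines(tsv)), 1)  # header only
})
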
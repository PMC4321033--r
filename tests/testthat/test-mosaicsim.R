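test_that("founder simulation hits its Poisson densities and is
           deterministic under seed", {
  lens <- c(chr1 = 1e6)
  cfg <- data.frame(name = c("donor", "bg", "nil"),
                    density = c(6, 0.013, 0))
  p1 <- simulate_founders(cfg, lens, seed = 3)
  p2 <- simulate_founders(cfg, lens, seed = 3)
  expect_equal(p1$donor$variants, p2$donor$variants)
  expect_equal(p1$bg$variants, p2$bg$variants)

  # density 6/kb on 1 Mb: count within Poisson(6000) +- 4 sigma
  expect_lt(abs(length(p1$donor) - 6000), 4 * sqrt(6000))
  expect_equal(length(p1$nil), 0)

  # different seed, different realization
  p3 <- simulate_founders(cfg, lens, seed = 4)
  expect_false(identical(p1$donor$variants$pos, p3$donor$variants$pos))
})

test_that("shared-pool founders overlap at the configured rate", {
  lens <- c(chr1 = 2e6)
  cfg <- data.frame(name = c("a", "b"), density = c(3, 3),
                    private_frac = c(0.5, 0.5))
  p <- simulate_founders(cfg, lens, seed = 12)
  ov <- length(intersect_snps(p$a, p$b, "position+allele"))
  # each table is ~50% pool draws from a pool of ~9000 sites; expected
  # overlap = n_a_shared * n_b_shared / pool; just check it is
  # substantial and far above the ~0 of independent founders
  expect_gt(ov, 100)
  indep <- simulate_founders(data.frame(name = c("a", "b"),
                                        density = c(3, 3)), lens,
                             seed = 12)
  expect_lt(length(intersect_snps(indep$a, indep$b, "position+allele")),
            ov / 10)
})

test_that("the F1 is fully heterozygous and heterozygosity decays as
           0.5^g", {
  lens <- c(chr1 = 2e7, chr2 = 2e7)
  f1 <- simulate_pedigree(c("A", "B"), lens, generations_selfing = 0,
                          rates = 1.5, seed = 6)
  expect_equal(heterozygous_fraction(f1), 1)
  expect_equal(unname(f1$truth$n_meioses), 0)

  for (g in c(2, 4)) {
    het <- vapply(1:12, function(s)
      heterozygous_fraction(simulate_pedigree(
        c("A", "B"), lens, g, rates = 1.5, seed = s)), numeric(1))
    expect_equal(mean(het), 0.5^g, tolerance = 0.5)
  }
})

test_that("crossovers per meiosis average the configured rate", {
  lens <- c(chr1 = 3e7)
  tot <- 0; meio <- 0
  for (s in 1:20) {
    ped <- simulate_pedigree(c("A", "B"), lens, 250, rates = 1.7,
                             seed = s)
    tot <- tot + ped$truth$true_crossovers[["chr1"]]
    meio <- meio + ped$truth$n_meioses
  }
  expect_equal(tot / meio, 1.7, tolerance = 0.1 / 1.7)
})

test_that("trisomy configuration is recorded as a third homolog", {
  lens <- c(chr1 = 1e7, chr3 = 1e7)
  ped <- simulate_pedigree(c("A", "B"), lens, 3, rates = 1.5, seed = 2,
                           trisomy = list(chrom = "chr3",
                                          at_generation = 0))
  expect_equal(unname(ped$copy_number), c(2L, 3L))
  expect_equal(length(ped$homologs$chr3), 3)
  expect_equal(length(ped$homologs$chr1), 2)
})

test_that("emitted SNP tables realize the genome's homozygous content", {
  lens <- c(chr1 = 2e6)
  panel <- simulate_founders(data.frame(name = c("A", "B"),
                                        density = c(2, 2)), lens,
                             seed = 13)
  # single-founder genome with no error -> exactly that founder's table
  g <- mosaic_from_blocks(data.frame(chrom = "chr1", left = 1,
                                     right = 2e6), lens,
                          donor = "A", background = "B")
  em <- emit_snp_table(g, panel, seed = 14)
  expect_equal(em$table$variants[c("chrom", "pos", "ref", "alt")],
               panel$A$variants[c("chrom", "pos", "ref", "alt")])
  expect_equal(em$truth_blocks$founder, "A")

  # fn_rate 1 empties the table; fp_rate adds Poisson-rate noise
  expect_equal(length(emit_snp_table(g, panel, fn_rate = 1,
                                     seed = 15)$table), 0)
  fp <- emit_snp_table(g, panel, fn_rate = 1, fp_rate = 0.5,
                       seed = 16)$table
  expect_lt(abs(length(fp) - 1000), 4 * sqrt(1000))

  # heterozygous regions are dropped with a warning
  f1 <- simulate_pedigree(c("A", "B"), lens, 0, rates = 1.5, seed = 17)
  expect_warning(em0 <- emit_snp_table(f1, panel, seed = 18),
                 "heterozygous")
  expect_equal(length(em0$table), 0)
})

test_that("per-region emitted counts match planted Poisson expectations", {
  lens <- arabidopsis_chrom_lengths()["chr1"]
  panel <- simulate_founders(data.frame(name = c("est", "bg"),
                                        density = c(6, 0.013)), lens,
                             seed = 21)
  iv <- cs3227_intervals()
  iv <- iv[iv$chrom == "chr1", ]
  g <- mosaic_from_blocks(iv, lens, donor = "est", background = "bg")
  em <- emit_snp_table(g, panel, seed = 22)
  v <- em$table$variants
  for (i in seq_len(nrow(iv))) {
    n <- sum(v$pos >= iv$left[i] & v$pos <= iv$right[i])
    expected <- 6 * (iv$right[i] - iv$left[i]) / 1000
    expect_lt(abs(n - expected), 4 * sqrt(expected))
  }
})

test_that("depth emission respects copy number, dispersion and seed", {
  lens <- c(chr1 = 1e7, chr3 = 1e7)
  g <- mosaic_from_blocks(data.frame(chrom = character(),
                                     left = numeric(), right = numeric()),
                          lens, copy_number = c(chr3 = 3))
  d1 <- simulate_depth(g, 5000, mean_depth = 24, seed = 30)
  d2 <- simulate_depth(g, 5000, mean_depth = 24, seed = 30)
  expect_equal(d1, d2)
  m1 <- mean(d1$count[d1$chrom == "chr1"])
  m3 <- mean(d1$count[d1$chrom == "chr3"])
  expect_equal(m1, 24, tolerance = 0.03)
  expect_equal(m3, 36, tolerance = 0.03)
  # finite dispersion inflates variance beyond Poisson
  dn <- simulate_depth(g, 5000, mean_depth = 24, dispersion = 5,
                       seed = 31)
  expect_gt(var(dn$count[dn$chrom == "chr1"]), 24 * 2)
})

test_that("trace simulation is deterministic and respects its knobs", {
  tr1 <- simulate_traces(24, sigma = 0.2, n = 4, seed = 9)
  tr2 <- simulate_traces(24, sigma = 0.2, n = 4, seed = 9)
  expect_equal(tr1, tr2)
  # sigma = 0, damping = 0, flat baseline -> an exact cosine
  tr0 <- simulate_traces(24, amplitude = 2, damping = 0, sigma = 0,
                         n = 1, duration_h = 48, seed = 10)
  y <- tr0$trace_1
  expect_equal(max(y), 2, tolerance = 0.01)
  expect_equal(stats::fivenum(y)[3], 0, tolerance = 0.15)
  # polynomial baseline applied
  trb <- simulate_traces(24, sigma = 0, damping = 0,
                         baseline = c(10, 0.5), n = 1, seed = 11)
  expect_equal(trb$trace_1 - (10 + 0.5 * trb$hours),
               simulate_traces(24, sigma = 0, damping = 0, n = 1,
                               seed = 11)$trace_1, tolerance = 1e-9)
})
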
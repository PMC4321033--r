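---
title: "Genetic archaeology of inbred stocks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic archaeology of inbred stocks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicpaint)
```

`mosaicpaint` answers four questions about an inbred genetic stock from
its resequencing data and phenotype records: *which parts of its genome
come from where* (ancestry painting), *how many generations separate it
from an outcross* (crossover and meiosis bounds), *what is its
karyotype* (normalized read depth), and *what are its rhythm and
segregation phenotypes worth statistically* (damped-cosine fits, exact
binomial tests). This vignette explains each model, the tunable
parameters and why their defaults are what they are, what the bundled
simulator does and does not emulate, and the numerical corner cases.

## The data model

All genomic modules operate on `snp_table` objects: per-sample lists of
homozygous SNP calls against one shared reference genome, sorted by
(chromosome, position), 1-based coordinates, at most one record per
site. This is the natural observable for inbred material — after
enough selfing a genome is homozygous almost everywhere, so a single
list of homozygous differences from the reference essentially *is* the
genotype. Heterozygous VCF records are rejected on input rather than
silently kept, because every downstream computation assumes the
homozygous model; indels are tolerated for I/O but excluded from
density and painting, which are defined on SNPs. BED output converts to
0-based half-open coordinates; everything internal stays 1-based
inclusive.

## Ancestry painting

An introgressed segment from a divergent accession announces itself by
SNP density: a reference-like background carries on the order of
10–30 SNPs per Mb (residual divergence between sibling lab stocks),
while a distinct natural accession differs at several SNPs per kb —
a contrast of two to three orders of magnitude. Painting therefore
needs no hidden Markov machinery; a threshold classifier on windowed
density, followed by merging, is fully separable at this contrast. An
HMM would only matter for donors barely diverged from the
background, which is outside this package's scope (an explicit
extension point, not a default).

The steps and their parameters:

1. **`window_density`** — windows of `window_bp` (default 100 kb)
   every `step_bp` (default 50 kb). At 100 kb, a background window
   expects below one SNP while a donor window expects hundreds, so the
   two classes cannot be confused; 100 kb also keeps window counts in
   the thousands genome-wide. Smaller windows (10 kb) trade
   breakpoint resolution against noise and are useful to resolve
   sub-window features such as a ~14 kb reference-like gap between two
   adjacent donor blocks.
2. **`donor_share`** — for each window with at least `min_snps`
   (default 5) query SNPs, the fraction of those SNPs each panel
   accession also carries (position *and* allele). The true donor
   shares nearly all of them; an unrelated accession of equal
   diversity shares close to none. Windows below `min_snps` are
   flagged undefined rather than scored on noise.
3. **`segment_ancestry`** — a window is donor-like iff density ≥ `d*`
   (default 1 SNP/kb, the geometric middle of the two regimes) and
   best share ≥ `s*` (default 0.8; the observed separation is ~1.0 vs
   ~0.0, so anything in (0.5, 0.95) behaves identically). Donor runs
   shorter than `min_block_bp` (default 200 kb, two default windows)
   are returned to the background label; gaps up to `merge_gap_bp`
   (default 20 kb) between same-donor blocks are closed. Undefined
   windows inherit the flanking consensus, which resolves to the
   reference label — the conservative direction, since claiming
   introgression is the stronger statement.
4. **`refine_breakpoints`** — window borders overshoot by up to one
   window; the refined border is the outermost query SNP inside the
   block that the donor also carries. At donor-level densities this
   localizes borders to a few hundred bp. The true breakpoint lies
   between the last donor-supporting marker and the first
   background-supporting one; reporting the outermost supporting
   marker (rather than the midpoint) makes the reported border an
   actual observed coordinate. A midpoint convention would differ by
   half the local marker spacing — negligible at donor densities.

Painting is deterministic given inputs and parameters.

## Crossover and meiosis bounds

Each interior boundary between reference-like and donor-like ancestry
in a surviving homozygous genome is the footprint of at least one
historical crossover, so the number of interior boundaries lower-bounds
the number of independent crossover events
(`count_min_crossovers`). Boundaries within `end_tolerance_bp`
(default 100 kb) of a chromosome end are not counted: a donor block
running into the telomere requires no crossover on that side, and
published interval sets routinely end a few hundred bp short of the
assembly end. With an expected crossover rate of λ_c per meiosis on
chromosome c (for *A. thaliana* chromosome 1, about 1.7), k_c observed
crossovers require at least ⌈k_c/λ_c⌉ meioses (`min_meioses`) — the
arithmetic behind "this stock must be many generations removed from
its outcross". Both bounds are conservative by construction: blocks
can merge and crossovers can be lost during inbreeding, so the
simulator's true crossover count is never below the bound (a property
the test suite checks against simulated pedigrees).

Whether two nearby donor blocks represent one or two introgression
events is not decidable from the final genome; the `merge_gap_bp`
setting exposes the choice, and both counts are reported in the tests.

## Karyotype from normalized read depth

`normalized_read_counts` divides each chromosome's typical per-site
read count by the genome-wide typical count. For a disomic chromosome
this ratio is ~1. A trisomic chromosome's raw mean is 1.5× the disomic
mean, but the elevation also inflates the genome-wide statistic: in
mean mode the expected ratio is 1.5/(1 + 0.5·w_c), where w_c is the
fraction of evaluated sites on chromosome c — between 1.36 and 1.5 in
practice. The default thresholds (`tri_low = 1.2`,
`mono_high = 0.75`) sit midway between these expectations and the
disomic 1. The default statistic is the median (robust to site-level
mapping-rate outliers, e.g. where donor-derived reads map poorly to
the reference); the mean mode is kept because it satisfies the exact
identity Σ_c r_c·w_c = 1 and the closed forms above. Whether to
evaluate all sites or only those inside donor-like blocks is exposed
via the `sites` filter; restricting to donor blocks compares
like-with-like when the query's divergent regions map at different
rates. Chromosomes with no evaluated sites are called `ambiguous` and
excluded from the normalizer; with per-chromosome depth statistics in
hand, the two thresholds partition the rest of the ratio axis, so
`ambiguous` does not otherwise occur.

## Transmission and segregation arithmetic

Trisomic chromosomes transmit to only a fraction of selfed offspring;
the classical basis count for chromosome-3 trisomics is 5 of 18
(27.8%), and `transmission_model` simply treats that fraction as a
binomial success probability. `transmission_expectation` reports the
real expectation and its integer bracket (106 offspring expect
29.44…, bracketed by 29–30) rather than choosing one integer.
`transmission_test` and `f2_segregation` are exact binomial tests; the
two-sided p-value follows the minimum-likelihood-sum definition (the
same as `stats::binom.test`, stated explicitly because two-sided exact
definitions differ between packages). Extreme outcomes underflow
double precision — 106/106 transmissions against f = 5/18 has
p = (5/18)^106 ≈ 10^-59 — so the natural-log p-value is always
computed alongside, by log-sum-exp over the same outcome set, and no
result is ever printed as a literal zero. `cosegregation` reports the
concordance fraction of two phenotype vectors plus Fisher's exact test
of independence; phenotypes caused by one lesion give concordance 1
and reject independence from roughly two dozen F2 individuals.

## Circadian parameter estimation

Luminescence reporter traces under constant conditions are
well-described by a damped cosine over a decaying baseline:

y(t) = baseline(t) + A·e^(−λt)·cos(2π(t−φ)/τ) + ε.

`fit_rhythm` removes a polynomial baseline (order 2 by default,
because reporter signal decays non-linearly over days), locates the
dominant periodogram peak inside the period band (default 15–35 h,
bracketing plant circadian periods with margin), and uses it to seed a
full nonlinear least-squares fit of all parameters, with the cosine
parameterized as a·cos + b·sin to avoid phase wrap-around. The
amplitude A is the cosine coefficient, *not* peak-to-trough (which is
2A); group comparisons are unaffected by this factor, but absolute
amplitudes from other software may differ by exactly 2, which is why
absolute amplitude is not treated as a comparable quantity here.

The **relative amplitude error** is defined in this package as the
half-width of the amplitude's approximate 95% confidence interval
(delta method on the (a, b) covariance) divided by the amplitude,
clipped to [0, 1]. This matches the statistic's defining limits — 0
for a noiseless sinusoid, approaching 1 when the amplitude is not
distinguishable from noise — and on realistic noise levels produces
values in the 0.1–0.4 range typical of published tables. Classic
FFT-NLLS implementations are not publicly specified at byte level, so
no numerical identity with them is claimed; the definition here is the
package's own and is stated wherever RAE is reported. A trace is
flagged rhythmic when RAE < `rae_max` (default 0.6, leaving headroom
above the ~0.4 of a weak but real rhythm). Traces shorter than 48 h or
24 samples are refused: two full cycles is the minimum for a
meaningful period CI.

Numerical notes: the periodogram is zero-padded 8× for peak
resolution; the damping rate is box-constrained to [−0.2, 0.5]/h
(beyond which the "rhythm" is a transient); a singular fit or absent
in-band peak yields `rhythmic = FALSE` with RAE 1 rather than an
error; on a noiseless input the residual variance is ~0 and RAE
evaluates to ~0, the correct limit.

## The simulator and what it does (not) emulate

`mosaicsim`-style generators exist so every claim above can be tested
against known truth:

- **`simulate_founders`** plants Poisson-process SNPs per chromosome.
  Defaults used throughout the tests: donor 6 SNPs/kb and background
  0.013 SNPs/kb, chosen so a ~30 Mb chromosome yields order 10^4–10^5
  donor SNPs against order 10^2 background SNPs — the observed
  contrast between a divergent accession and a reference-like sibling
  stock. These are simulator conventions, not estimates for any real
  accession.
- **`simulate_pedigree`** crosses two founders and selfs by
  single-seed descent (one offspring per generation, mirroring
  seed-to-seed stock propagation; population-level selfing is not
  simulated). Each meiosis places Poisson(λ_c) crossovers uniformly —
  no crossover interference, because every downstream statement uses
  expected counts only. Per-locus heterozygosity decays as 0.5^g, and
  the recorded ground truth (crossovers per chromosome over the
  surviving lineage's 2g meioses) backs the lower-bound tests.
  Trisomy is introduced by duplicating one homolog at a configured
  generation and is retained deterministically; the classical
  alternative orderings of outcross, mutation and trisomy induction
  differ only in event order, which a single final genome cannot
  distinguish, so they are configuration presets rather than
  distinguishable models.
- **`emit_snp_table`** realizes the sequencing observable: founder
  SNPs inside homozygous intervals, optionally thinned (false
  negatives) and salted (false positives); heterozygous residue is
  dropped with a warning, as a homozygous-call pipeline would.
- **`simulate_depth`** draws per-site counts as negative binomial with
  mean `mean_depth · copy_number/2` (Poisson in the infinite-dispersion
  default), emulating ~20–30× whole-genome coverage.
- **`simulate_traces`** generates damped cosines with per-trace random
  phase and Gaussian noise.

Not emulated: read-level artifacts (mapping bias, duplicates, GC),
genotyping error correlated with divergence, structural variation,
crossover interference and hotspots, segregation distortion, and
population structure within accessions. Passing recovery tests
therefore demonstrates the *inference logic* is correct under the
stated generative model, not that real data are free of these
complications; on real data the density contrast and depth ratios are
strong enough that the same thresholds are expected to apply, but
borders inherit any local mapping pathology.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale by design:
painting worlds of one to five chromosomes at real chromosome lengths
(simulated SNP tables up to ~10^5 records), depth tracks of 10^4 sites
per chromosome, 12-trace rhythm batches of 120 hourly samples, and
10–50 simulated pedigrees per property. Every stochastic component
takes an explicit integer seed, and identical (configuration, seed)
pairs reproduce bit-identical outputs; the acceptance script derives
all its randomness from its `--seed` argument.

## Known limitations

- Painting assumes exactly one donor per block; mosaic blocks from two
  different donors separated by less than a window blur into the
  better-scoring donor.
- Donor identification is only as good as the panel: a missing true
  donor yields high-density blocks with low best-share, which the
  defaults then conservatively label reference-like.
- The meiosis bound assumes the supplied λ_c; it scales inversely with
  that rate and is a bound, not an estimate.
- Karyotype calls are whole-chromosome only; segmental aneuploidy is
  out of scope.
- RAE values are comparable within this package but not numerically
  interchangeable with other rhythm-analysis software (see above).
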
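#' Simulate founder accession SNP tables
#'
#' Each founder receives SNPs vs the common reference as a Poisson
#' process along every chromosome at its own density; alleles are drawn
#' uniformly among the three non-reference bases. A fraction
#' `1 - private_frac` of each founder's SNPs is drawn from a shared
#' species-wide pool (identical position and alleles across founders),
#' so that panel decoys can share variation with a donor at a
#' controlled rate; `private_frac = 1` makes founders independent.
#'
#' This emulates the empirical two-density world of resequenced inbred
#' stocks: a reference-like background of a few hundred SNPs per
#' chromosome versus a divergent accession with 10-200 times more.
#'
#' @param founders data.frame with columns `name`, `density` (SNPs per
#'   kb) and optionally `private_frac` in \[0, 1\] (default 1).
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param seed Integer seed; the whole panel is reproducible under it.
#' @return An [accession_panel()].
#' @export
simulate_founders <- function(founders, chrom_lengths, seed) {
  stopifnot(all(c("name", "density") %in% names(founders)),
            all(founders$density >= 0))
  if (!"private_frac" %in% names(founders)) founders$private_frac <- 1
  names(chrom_lengths) <- normalize_chrom(names(chrom_lengths))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rand_site <- function(n, len, ch) {
    pos <- sort(sample.int(len, n))
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    data.frame(chrom = ch, pos = pos, ref = ref, alt = unname(alt),
               stringsAsFactors = FALSE)
  }
  # lazily built shared pool, dense enough to serve all founders
  pool_density <- max(founders$density) * 1.5
  pool <- if (any(founders$private_frac < 1)) {
    do.call(rbind, lapply(names(chrom_lengths), function(ch) {
      len <- chrom_lengths[[ch]]
      rand_site(stats::rpois(1, pool_density * len / 1000), len, ch)
    }))
  } else NULL
  tabs <- lapply(seq_len(nrow(founders)), function(i) {
    dens <- founders$density[i]; pf <- founders$private_frac[i]
    v <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
      len <- chrom_lengths[[ch]]
      n <- stats::rpois(1, dens * len / 1000)
      n_shared <- round((1 - pf) * n)
      parts <- list()
      if (n_shared > 0 && !is.null(pool)) {
        cand <- which(pool$chrom == ch)
        take <- cand[sample.int(length(cand), min(n_shared, length(cand)))]
        parts$shared <- pool[take, , drop = FALSE]
      }
      n_priv <- n - if (is.null(parts$shared)) 0 else nrow(parts$shared)
      if (n_priv > 0) parts$priv <- rand_site(n_priv, len, ch)
      if (!length(parts)) return(NULL)
      do.call(rbind, parts)
    }))
    if (is.null(v))
      v <- data.frame(chrom = character(), pos = numeric(),
                      ref = character(), alt = character())
    v <- v[!duplicated(v[c("chrom", "pos")]), , drop = FALSE]
    snp_table(v, founders$name[i], normalize = FALSE)
  })
  names(tabs) <- founders$name
  accession_panel(tabs)
}

# one meiotic gamete from a pair of homologs: Poisson(rate) crossovers
# placed uniformly, chromatid start chosen at random. Homologs and the
# returned gamete are interval tables (start, end, founder), 0-based
# half-open partitions of [0, len).
draw_gamete <- function(hom1, hom2, len, rate) {
  ncross <- stats::rpois(1, rate)
  cuts <- sort(stats::runif(ncross, 0, len))
  bounds <- c(0, cuts, len)
  use_first <- sample(c(TRUE, FALSE), 1)
  segs <- lapply(seq_len(length(bounds) - 1), function(k) {
    src <- if (xor(use_first, k %% 2 == 0)) hom1 else hom2
    clip_intervals(src, bounds[k], bounds[k + 1])
  })
  g <- do.call(rbind, segs)
  list(intervals = simplify_intervals(g), ncross = ncross)
}

clip_intervals <- function(iv, lo, hi) {
  keep <- iv$end > lo & iv$start < hi
  out <- iv[keep, , drop = FALSE]
  out$start <- pmax(out$start, lo)
  out$end <- pmin(out$end, hi)
  out
}

simplify_intervals <- function(iv) {
  if (nrow(iv) < 2) return(iv)
  iv <- iv[order(iv$start), , drop = FALSE]
  keep <- list(iv[1, ])
  for (k in 2:nrow(iv)) {
    j <- length(keep)
    if (iv$founder[k] == keep[[j]]$founder &&
        abs(iv$start[k] - keep[[j]]$end) < 1e-9) {
      keep[[j]]$end <- iv$end[k]
    } else keep[[length(keep) + 1]] <- iv[k, ]
  }
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out
}

#' Simulate an outcross-plus-selfing pedigree
#'
#' Crosses two inbred founders (F1 fully heterozygous) and propagates
#' by single-seed descent for `generations_selfing` generations: each
#' generation the next individual is formed from two independent
#' gametes of the previous one. Each meiosis places Poisson(`rate_c`)
#' crossovers uniformly along chromosome `c` — no interference, since
#' the downstream pedigree arithmetic only uses expected counts.
#' Optionally one chromosome is made trisomic at a configured
#' generation by duplicating one homolog; the extra copy is retained to
#' the end (the final copy number is ground truth for karyotype
#' recovery tests). The three classical orderings of outcross, mutation
#' and trisomy induction differ only in event order, which is
#' unobservable from the final genome; they correspond to choosing
#' `trisomy_at` before or after generation 0.
#'
#' @param founder_names Character vector of exactly 2 founder names;
#'   the first is the homolog carried by the maternal side of the F1.
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param generations_selfing Number of selfing generations g >= 0.
#' @param rates Named per-chromosome expected crossovers per meiosis
#'   (recycled from a scalar).
#' @param seed Integer seed.
#' @param trisomy Optional list `list(chrom =, at_generation =)`
#'   duplicating one homolog of `chrom` after that selfing generation
#'   (0 = at F1).
#' @return Object of class `mosaic_genome`: per chromosome a list of
#'   homolog interval tables (`start`, `end`, `founder`; 0-based
#'   half-open partitions of the chromosome), `copy_number` per
#'   chromosome, and ground truth `truth` with `n_meioses` and
#'   `true_crossovers` per chromosome summed over the surviving
#'   lineage's meioses.
#' @export
simulate_pedigree <- function(founder_names, chrom_lengths,
                              generations_selfing, rates, seed,
                              trisomy = NULL) {
  stopifnot(length(founder_names) == 2, generations_selfing >= 0)
  names(chrom_lengths) <- normalize_chrom(names(chrom_lengths))
  if (length(rates) == 1 && is.null(names(rates)))
    rates <- stats::setNames(rep(rates, length(chrom_lengths)),
                             names(chrom_lengths))
  names(rates) <- normalize_chrom(names(rates))
  stopifnot(all(rates[names(chrom_lengths)] > 0))
  set.seed(seed)
  whole <- function(ch, f) data.frame(start = 0,
                                      end = chrom_lengths[[ch]],
                                      founder = f,
                                      stringsAsFactors = FALSE)
  indiv <- lapply(names(chrom_lengths), function(ch)
    list(whole(ch, founder_names[1]), whole(ch, founder_names[2])))
  names(indiv) <- names(chrom_lengths)
  true_cross <- stats::setNames(numeric(length(chrom_lengths)),
                                names(chrom_lengths))
  copy_number <- stats::setNames(rep(2L, length(chrom_lengths)),
                                 names(chrom_lengths))
  extra <- NULL
  maybe_trisomy <- function(gen) {
    if (!is.null(trisomy) && trisomy$at_generation == gen) {
      ch <- normalize_chrom(trisomy$chrom)
      copy_number[[ch]] <<- 3L
      extra <<- indiv[[ch]][[sample(1:2, 1)]]
    }
  }
  maybe_trisomy(0)
  g <- generations_selfing
  if (g > 0) for (gen in seq_len(g)) {
    nxt <- lapply(names(chrom_lengths), function(ch) {
      len <- chrom_lengths[[ch]]
      g1 <- draw_gamete(indiv[[ch]][[1]], indiv[[ch]][[2]], len,
                        rates[[ch]])
      g2 <- draw_gamete(indiv[[ch]][[1]], indiv[[ch]][[2]], len,
                        rates[[ch]])
      true_cross[[ch]] <<- true_cross[[ch]] + g1$ncross + g2$ncross
      list(g1$intervals, g2$intervals)
    })
    names(nxt) <- names(chrom_lengths)
    indiv <- nxt
    maybe_trisomy(gen)
  }
  if (!is.null(extra)) {
    ch <- normalize_chrom(trisomy$chrom)
    indiv[[ch]][[3]] <- extra
  }
  structure(list(chrom_lengths = chrom_lengths, homologs = indiv,
                 copy_number = copy_number,
                 truth = list(n_meioses = 2L * generations_selfing,
                              true_crossovers = true_cross)),
            class = "mosaic_genome")
}

#' Build a homozygous mosaic genome from explicit donor intervals
#'
#' Constructs the `mosaic_genome` that an idealized recombinant inbred
#' line would carry: homozygous donor ancestry inside the given
#' intervals, homozygous recurrent-parent ancestry elsewhere. Useful
#' for planting published interval sets as simulation truth.
#'
#' @param intervals data.frame with `chrom`, `left`, `right` (1-based
#'   inclusive donor intervals).
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param donor,background Founder names for inside/outside the
#'   intervals.
#' @param copy_number Optional named vector of per-chromosome copy
#'   numbers (default 2).
#' @return A `mosaic_genome` (with empty crossover truth).
#' @export
mosaic_from_blocks <- function(intervals, chrom_lengths,
                               donor = "donor", background = "ref",
                               copy_number = NULL) {
  names(chrom_lengths) <- normalize_chrom(names(chrom_lengths))
  intervals$chrom <- normalize_chrom(intervals$chrom)
  homs <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    iv <- iv[order(iv$left), , drop = FALSE]
    segs <- list(); prev <- 0
    for (i in seq_len(nrow(iv))) {
      s <- max(0, iv$left[i] - 1); e <- min(len, iv$right[i])
      if (s > prev)
        segs[[length(segs) + 1]] <- data.frame(start = prev, end = s,
                                               founder = background)
      segs[[length(segs) + 1]] <- data.frame(start = s, end = e,
                                             founder = donor)
      prev <- e
    }
    if (prev < len)
      segs[[length(segs) + 1]] <- data.frame(start = prev, end = len,
                                             founder = background)
    hom <- do.call(rbind, segs)
    list(hom, hom)
  })
  names(homs) <- names(chrom_lengths)
  cn <- stats::setNames(rep(2L, length(chrom_lengths)),
                        names(chrom_lengths))
  if (!is.null(copy_number)) cn[normalize_chrom(names(copy_number))] <-
    as.integer(copy_number)
  structure(list(chrom_lengths = chrom_lengths, homologs = homs,
                 copy_number = cn,
                 truth = list(n_meioses = NA_integer_,
                              true_crossovers = NULL)),
            class = "mosaic_genome")
}

#' Homozygous founder intervals of a mosaic genome
#'
#' Intersects the two primary homologs: intervals where both carry the
#' same founder label. These are the regions whose SNPs are emitted as
#' homozygous calls, and (for the donor founder) the truth blocks that
#' painting should recover.
#'
#' @param genome A `mosaic_genome`.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open),
#'   `founder`.
#' @export
homozygous_intervals <- function(genome) {
  out <- lapply(names(genome$homologs), function(ch) {
    h1 <- genome$homologs[[ch]][[1]]; h2 <- genome$homologs[[ch]][[2]]
    cuts <- sort(unique(c(h1$start, h1$end, h2$start, h2$end)))
    segs <- data.frame(start = cuts[-length(cuts)], end = cuts[-1])
    mid <- (segs$start + segs$end) / 2
    lab1 <- founder_at(h1, mid)
    lab2 <- founder_at(h2, mid)
    segs$founder <- ifelse(lab1 == lab2, lab1, NA_character_)
    segs <- segs[!is.na(segs$founder), , drop = FALSE]
    if (!nrow(segs)) return(NULL)
    segs$chrom <- ch
    simplify_intervals(segs[c("start", "end", "founder", "chrom")])
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), founder = character()))
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[c("chrom", "start", "end", "founder")]
}

founder_at <- function(hom, pos) {
  idx <- findInterval(pos, hom$start)
  hom$founder[pmax(idx, 1)]
}

#' Length-weighted heterozygous fraction of a mosaic genome
#'
#' After g generations of selfing the expected per-locus
#' heterozygosity is 0.5^g; this returns the realized fraction of the
#' genome where the two homologs carry different founder labels.
#'
#' @param genome A `mosaic_genome`.
#' @return Fraction in \[0, 1\].
#' @export
heterozygous_fraction <- function(genome) {
  hom_len <- sum(vapply(names(genome$homologs), function(ch) {
    hz <- homozygous_intervals_chr(genome, ch)
    sum(hz$end - hz$start)
  }, numeric(1)))
  total <- sum(genome$chrom_lengths)
  1 - hom_len / total
}

homozygous_intervals_chr <- function(genome, ch) {
  h1 <- genome$homologs[[ch]][[1]]; h2 <- genome$homologs[[ch]][[2]]
  cuts <- sort(unique(c(h1$start, h1$end, h2$start, h2$end)))
  segs <- data.frame(start = cuts[-length(cuts)], end = cuts[-1])
  mid <- (segs$start + segs$end) / 2
  segs[founder_at(h1, mid) == founder_at(h2, mid), , drop = FALSE]
}

#' Emit the observable SNP table of a mosaic genome
#'
#' The sequenced observable of a recombinant inbred genome: homozygous
#' regions contribute the resident founder's SNPs as homozygous calls;
#' heterozygous regions are dropped with a warning (the calling model
#' covers homozygous inbred sites only). Optional error layers thin
#' true SNPs (false negatives) and sprinkle false positives.
#'
#' @param genome A `mosaic_genome`.
#' @param panel [accession_panel()] holding the founders' SNP tables.
#' @param fn_rate Per-SNP false-negative (drop) probability.
#' @param fp_rate False positives per kb, placed uniformly with random
#'   alleles.
#' @param seed Integer seed.
#' @param sample_name Name for the emitted table.
#' @return List with `table` (the emitted [snp_table()]) and
#'   `truth_blocks` (`ancestry_blocks`-shaped truth: 1-based inclusive
#'   homozygous intervals labeled by founder).
#' @export
emit_snp_table <- function(genome, panel, fn_rate = 0, fp_rate = 0,
                           seed = 1, sample_name = "query") {
  stopifnot(fn_rate >= 0, fn_rate <= 1, fp_rate >= 0)
  set.seed(seed)
  hz <- homozygous_intervals(genome)
  het_frac <- heterozygous_fraction(genome)
  if (het_frac > 1e-9)
    warning(sprintf(
      "%.1f%% of the genome is heterozygous and was dropped", 100 * het_frac))
  rows <- list()
  for (i in seq_len(nrow(hz))) {
    f <- hz$founder[i]
    if (!f %in% names(panel)) next
    fv <- panel[[f]]$variants
    inreg <- fv$chrom == hz$chrom[i] & fv$pos > hz$start[i] &
      fv$pos <= hz$end[i]
    rows[[length(rows) + 1]] <- fv[inreg, , drop = FALSE]
  }
  v <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE))) else
      data.frame(chrom = character(), pos = numeric(),
                 ref = character(), alt = character(),
                 support = numeric())
  if (fn_rate > 0 && nrow(v))
    v <- v[stats::runif(nrow(v)) >= fn_rate, , drop = FALSE]
  if (fp_rate > 0) {
    bases <- c("A", "C", "G", "T")
    fps <- do.call(rbind, lapply(names(genome$chrom_lengths), function(ch) {
      len <- genome$chrom_lengths[[ch]]
      n <- stats::rpois(1, fp_rate * len / 1000)
      if (!n) return(NULL)
      ref <- sample(bases, n, replace = TRUE)
      data.frame(chrom = ch, pos = sample.int(len, n), ref = ref,
                 alt = vapply(ref, function(r)
                   sample(setdiff(bases, r), 1), ""),
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(fps)) {
      fps$support <- NA_real_
      if (!"support" %in% names(v)) v$support <- NA_real_
      v <- rbind(v, fps[names(v)])
    }
  }
  v <- v[!duplicated(v[c("chrom", "pos")]), , drop = FALSE]
  truth <- data.frame(chrom = hz$chrom, left = hz$start + 1,
                      right = hz$end, founder = hz$founder,
                      stringsAsFactors = FALSE)
  list(table = snp_table(v, sample_name, normalize = FALSE),
       truth_blocks = truth)
}

#' Simulate a read-depth track over a mosaic genome
#'
#' Per-site counts are negative binomial with mean
#' `mean_depth * copy_number / 2` and size `dispersion`
#' (`dispersion = Inf` gives the Poisson limit), emulating
#' whole-genome-sequencing coverage of a (possibly trisomic) stock.
#'
#' @param genome A `mosaic_genome`.
#' @param sites_per_chrom Evaluated sites per chromosome (uniformly
#'   placed), or a data.frame `chrom`, `pos` of explicit sites.
#' @param mean_depth Genome-average haploid-pair depth (e.g. 24).
#' @param dispersion Negative-binomial size parameter (default Inf =
#'   Poisson).
#' @param seed Integer seed.
#' @return A [depth_track()].
#' @export
simulate_depth <- function(genome, sites_per_chrom = 1e4, mean_depth = 24,
                           dispersion = Inf, seed = 1) {
  stopifnot(mean_depth > 0)
  set.seed(seed)
  sites <- if (is.data.frame(sites_per_chrom)) sites_per_chrom else
    do.call(rbind, lapply(names(genome$chrom_lengths), function(ch)
      data.frame(chrom = ch,
                 pos = sort(sample.int(genome$chrom_lengths[[ch]],
                                       sites_per_chrom)))))
  mu <- mean_depth * genome$copy_number[sites$chrom] / 2
  sites$count <- if (is.infinite(dispersion))
    stats::rpois(nrow(sites), mu) else
      stats::rnbinom(nrow(sites), size = dispersion, mu = mu)
  depth_track(sites)
}

#' Simulate damped sinusoidal rhythm traces
#'
#' `y_i(t) = baseline(t) + A * exp(-damping * t) *
#' cos(2*pi*(t - phase_i)/period) + N(0, sigma^2)` with an independent
#' uniform random phase per trace, emulating luminescence reporter time
#' courses under constant conditions.
#'
#' @param period True free-running period (h).
#' @param amplitude True cosine amplitude A.
#' @param damping Exponential damping rate per hour.
#' @param sigma Gaussian noise SD.
#' @param baseline Polynomial baseline coefficients (constant first;
#'   default 0).
#' @param n Number of traces.
#' @param duration_h Trace length (h).
#' @param step_h Sampling interval (h).
#' @param seed Integer seed.
#' @return Wide data.frame: `hours` plus columns `trace_1 .. trace_n`.
#' @export
simulate_traces <- function(period, amplitude = 1, damping = 0.01,
                            sigma = 0.2, baseline = 0, n = 12,
                            duration_h = 120, step_h = 1, seed = 1) {
  stopifnot(period > 0, n >= 1)
  set.seed(seed)
  t <- seq(0, duration_h, by = step_h)
  base <- rowSums(vapply(seq_along(baseline), function(k)
    baseline[k] * t^(k - 1), numeric(length(t))))
  out <- data.frame(hours = t)
  for (i in seq_len(n)) {
    phi <- stats::runif(1, 0, period)
    out[[paste0("trace_", i)]] <- base +
      amplitude * exp(-damping * t) * cos(2 * pi * (t - phi) / period) +
      stats::rnorm(length(t), 0, sigma)
  }
  out
}
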
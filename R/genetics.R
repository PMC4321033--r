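#' Transmission model from a historical basis count
#'
#' Trisomic chromosomes pass to only a fraction of selfed offspring;
#' classical counts for chromosome-3 trisomics give 5 transmissions in
#' 18 offspring (27.8%). The model simply records the basis fraction
#' `k / n_basis` used as the binomial success probability in
#' expectations and exact tests.
#'
#' @param k Basis successes (default 5).
#' @param n_basis Basis trials (default 18).
#' @return Object of class `transmission_model` with elements `k`,
#'   `n_basis`, `frequency`.
#' @examples
#' transmission_model()$frequency  # 0.2778
#' @export
transmission_model <- function(k = 5, n_basis = 18) {
  stopifnot(k >= 0, n_basis >= 1, k <= n_basis)
  structure(list(k = k, n_basis = n_basis, frequency = k / n_basis),
            class = "transmission_model")
}

#' Expected transmitted count among n offspring
#'
#' @param n Offspring count.
#' @param model A [transmission_model()].
#' @return List with `expected` (`n * frequency`, real) and `bracket`
#'   (the two integers flooring/ceiling it; a single integer when exact).
#' @examples
#' transmission_expectation(106, transmission_model())  # 29.44, [29, 30]
#' @export
transmission_expectation <- function(n, model = transmission_model()) {
  stopifnot(n >= 0, inherits(model, "transmission_model"))
  e <- n * model$frequency
  list(expected = e, bracket = unique(c(floor(e), ceiling(e))))
}

# log of the two-sided exact binomial p-value: sum of probabilities of
# all outcomes no more likely than the observed one (the same
# minimum-likelihood definition stats::binom.test uses), evaluated in
# log space so extreme results never underflow to zero.
log_binom_p <- function(observed, n, p, alternative) {
  ld <- stats::dbinom(0:n, n, p, log = TRUE)
  sel <- switch(alternative,
                greater = (0:n) >= observed,
                less = (0:n) <= observed,
                two.sided = ld <= ld[observed + 1] + 1e-7)
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  min(0, lse(ld[sel]))
}

#' Exact binomial test of trisomic transmission
#'
#' Tests an observed transmitted count against the model frequency with
#' an exact binomial test. The two-sided p-value uses the
#' minimum-likelihood-sum definition (as [stats::binom.test()]). The
#' natural-log p-value is always reported so that overwhelming results
#' are never printed as a literal zero.
#'
#' @param observed Observed count of the phenotype/genotype.
#' @param n Offspring scored.
#' @param model A [transmission_model()].
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return Object of class `segregation_result`: `observed`, `n`,
#'   `expected`, `frequency`, `p_value`, `log_p`, `alternative`,
#'   `model`.
#' @examples
#' transmission_test(106, 106, alternative = "greater")$log_p / log(10)
#' @export
transmission_test <- function(observed, n, model = transmission_model(),
                              alternative = c("two.sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  stopifnot(observed >= 0, observed <= n)
  f <- model$frequency
  bt <- stats::binom.test(observed, n, p = f, alternative = alternative)
  structure(list(observed = observed, n = n, expected = n * f,
                 frequency = f, p_value = bt$p.value,
                 log_p = log_binom_p(observed, n, f, alternative),
                 alternative = alternative, model = "transmission"),
            class = "segregation_result")
}

#' @exportS3Method base::print
print.segregation_result <- function(x, ...) {
  cat(x$model, "test: observed", x$observed, "of", x$n,
      sprintf("(expected %.2f)", x$expected), "\n")
  cat(sprintf("  p = %.4g (%s), log10 p = %.2f\n", x$p_value,
              x$alternative, x$log_p / log(10)))
  invisible(x)
}

#' Exact test of F2 Mendelian segregation
#'
#' A single recessive locus segregates 1 mutant : 3 wild type in an F2;
#' a dominant one 3 : 1. Tests observed mutant counts against that
#' expectation with an exact binomial test.
#'
#' @param observed_mutant Mutant individuals observed.
#' @param n F2 individuals scored.
#' @param model `"recessive"` (expected fraction 1/4) or `"dominant"`
#'   (3/4).
#' @param alternative Passed to the binomial test.
#' @return A `segregation_result` (see [transmission_test()]).
#' @export
f2_segregation <- function(observed_mutant, n,
                           model = c("recessive", "dominant"),
                           alternative = c("two.sided", "greater",
                                           "less")) {
  model <- match.arg(model)
  alternative <- match.arg(alternative)
  f <- if (model == "recessive") 1 / 4 else 3 / 4
  bt <- stats::binom.test(observed_mutant, n, p = f,
                          alternative = alternative)
  structure(list(observed = observed_mutant, n = n, expected = n * f,
                 frequency = f, p_value = bt$p.value,
                 log_p = log_binom_p(observed_mutant, n, f, alternative),
                 alternative = alternative,
                 model = paste0("F2 ", model)),
            class = "segregation_result")
}

#' Cosegregation of two phenotypes
#'
#' Two phenotypes caused by one and the same lesion cosegregate
#' perfectly; independent loci do not. Reports the concordance fraction
#' and Fisher's exact test of independence on the 2x2 table.
#'
#' @param pheno_a,pheno_b Equal-length logical vectors, one element per
#'   individual.
#' @return List with `concordance` (fraction with `a == b`), `table`
#'   (2x2 contingency table) and `p_value` (Fisher's exact,
#'   two-sided; NA when a phenotype is constant).
#' @export
cosegregation <- function(pheno_a, pheno_b) {
  if (length(pheno_a) != length(pheno_b))
    stop("phenotype vectors differ in length")
  if (!length(pheno_a)) stop("need at least one individual")
  a <- factor(as.logical(pheno_a), levels = c(FALSE, TRUE))
  b <- factor(as.logical(pheno_b), levels = c(FALSE, TRUE))
  tab <- table(a, b)
  p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    NA_real_ else stats::fisher.test(tab)$p.value
  list(concordance = mean(pheno_a == pheno_b), table = tab, p_value = p)
}
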
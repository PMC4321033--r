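#' Read rhythmic traces from a wide TSV
#'
#' First column is time in hours; every further column one well/trace.
#'
#' @param path TSV path.
#' @return data.frame with first column `hours`, one column per trace.
#' @export
read_traces <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  names(d)[1] <- "hours"
  if (is.unsorted(d$hours, strictly = TRUE))
    stop("hours must be strictly increasing")
  d
}

#' Fit a damped cosine to one circadian trace
#'
#' The model is
#' `y(t) = baseline(t) + A * exp(-damping * t) * cos(2*pi*(t - phase)/period)`,
#' with a polynomial baseline of order `detrend_order` absorbing the
#' slow drift typical of luminescence reporters. The trace is first
#' detrended and Fourier-analysed; the dominant spectral peak inside the
#' period band seeds a full nonlinear least-squares fit. The relative
#' amplitude error (RAE) is the half-width of the amplitude's
#' approximate 95% confidence interval divided by the amplitude,
#' clipped to \[0, 1\]: 0 for a perfect sinusoid, approaching 1 as the
#' rhythm drowns in noise. A trace is flagged rhythmic when
#' `RAE < rae_max`.
#'
#' @param hours Numeric vector of sampling times (hours), strictly
#'   increasing; traces spanning under 48 h or with fewer than 24
#'   samples are flagged unfittable.
#' @param values Signal values, same length.
#' @param band Two-element period search band in hours (default
#'   `c(15, 35)`).
#' @param detrend_order Baseline polynomial order (default 2).
#' @param rae_max RAE above which a trace is called arrhythmic
#'   (default 0.6).
#' @return Object of class `rhythm_fit`: `period` (h), `amplitude`
#'   (signal units, cosine coefficient), `phase` (h, in `[0, period)`),
#'   `damping` (per h), `baseline` (polynomial coefficients), `rae`,
#'   `rhythmic`, `flag` (`"ok"`, `"too_short"`, `"no_peak"` or
#'   `"singular"`).
#' @examples
#' t <- 0:119
#' fit <- fit_rhythm(t, cos(2 * pi * t / 24))
#' c(fit$period, fit$rae)
#' @export
fit_rhythm <- function(hours, values, band = c(15, 35), detrend_order = 2,
                       rae_max = 0.6) {
  stopifnot(length(hours) == length(values), band[1] < band[2],
            band[1] > 0)
  bad_fit <- function(flag) structure(
    list(period = NA_real_, amplitude = NA_real_, phase = NA_real_,
         damping = NA_real_, baseline = NULL, rae = 1, rhythmic = FALSE,
         flag = flag), class = "rhythm_fit")
  if (diff(range(hours)) < 48 || length(hours) < 24)
    return(bad_fit("too_short"))
  ok <- is.finite(values)
  hours <- hours[ok]; values <- values[ok]

  # detrend, then seed the period from a zero-padded periodogram
  base_fit <- if (detrend_order >= 1) {
    X <- stats::poly(hours, degree = detrend_order, raw = TRUE)
    stats::lm(values ~ X)
  } else stats::lm(values ~ 1)
  resid <- stats::residuals(base_fit)
  dt <- stats::median(diff(hours))
  nfft <- 2^ceiling(log2(length(resid) * 8))
  spec <- Mod(stats::fft(c(resid, rep(0, nfft - length(resid)))))^2
  freq <- seq(0, by = 1 / (nfft * dt), length.out = nfft)
  inband <- freq > 0 & 1 / freq >= band[1] & 1 / freq <= band[2]
  if (!any(inband) || all(spec[inband] == 0)) return(bad_fit("no_peak"))
  tau0 <- 1 / freq[inband][which.max(spec[inband])]

  # full damped-cosine least squares (a/b parameterization avoids
  # phase wrap-around)
  df <- data.frame(t = hours, y = values)
  bterms <- paste0("c", seq_len(detrend_order), " * t^",
                   seq_len(detrend_order), collapse = " + ")
  form <- stats::as.formula(paste(
    "y ~ c0 +", if (detrend_order >= 1) paste(bterms, "+") else "",
    "exp(-lam * t) * (a * cos(2*pi*t/tau) + b * sin(2*pi*t/tau))"))
  w <- 2 * pi / tau0
  cstart <- if (detrend_order >= 1)
    stats::setNames(as.list(unname(stats::coef(base_fit)[-1])),
                    paste0("c", seq_len(detrend_order))) else list()
  start <- c(list(c0 = unname(stats::coef(base_fit)[1])), cstart,
             list(a = 2 * mean(resid * cos(w * hours)),
                  b = 2 * mean(resid * sin(w * hours)),
                  lam = 0.005, tau = tau0))
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start,
                      lower = c(rep(-Inf, detrend_order + 3), -0.2, band[1]),
                      upper = c(rep(Inf, detrend_order + 3), 0.5, band[2]),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad_fit("singular"))
  cf <- stats::coef(fit)
  A <- sqrt(cf[["a"]]^2 + cf[["b"]]^2)
  tau <- cf[["tau"]]
  phase <- (tau / (2 * pi)) * atan2(cf[["b"]], cf[["a"]])
  phase <- phase %% tau
  # delta-method SE of A from the (a, b) covariance block
  se_A <- tryCatch({
    V <- stats::vcov(fit)[c("a", "b"), c("a", "b")]
    g <- c(cf[["a"]], cf[["b"]]) / max(A, .Machine$double.eps)
    sqrt(max(0, drop(t(g) %*% V %*% g)))
  }, error = function(e) NA_real_)
  rae <- if (!is.finite(se_A)) 1 else
    min(1, max(0, 1.96 * se_A / max(A, .Machine$double.eps)))
  structure(list(period = tau, amplitude = A, phase = phase,
                 damping = cf[["lam"]],
                 baseline = cf[grep("^c[0-9]+$", names(cf))],
                 rae = rae, rhythmic = rae < rae_max, flag = "ok"),
            class = "rhythm_fit")
}

#' @exportS3Method base::print
print.rhythm_fit <- function(x, ...) {
  if (x$flag != "ok") {
    cat("rhythm_fit: not fit (", x$flag, ")\n", sep = "")
  } else {
    cat(sprintf(
      "rhythm_fit: period %.2f h, amplitude %.3g, RAE %.3f (%s)\n",
      x$period, x$amplitude, x$rae,
      if (x$rhythmic) "rhythmic" else "arrhythmic"))
  }
  invisible(x)
}

#' Fit every trace of a wide table
#'
#' @param traces Wide data.frame as from [read_traces()] or
#'   [simulate_traces()]: first column hours, one column per trace.
#' @inheritParams fit_rhythm
#' @return data.frame with one row per trace: `id`, `period`,
#'   `amplitude`, `phase`, `damping`, `rae`, `rhythmic`, `flag`.
#' @export
fit_rhythms <- function(traces, band = c(15, 35), detrend_order = 2,
                        rae_max = 0.6) {
  hours <- traces[[1]]
  ids <- names(traces)[-1]
  rows <- lapply(ids, function(id) {
    f <- fit_rhythm(hours, traces[[id]], band, detrend_order, rae_max)
    data.frame(id = id, period = f$period, amplitude = f$amplitude,
               phase = f$phase, damping = f$damping, rae = f$rae,
               rhythmic = f$rhythmic, flag = f$flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Group summary of rhythm fits
#'
#' Means and standard errors of period, amplitude and RAE per genotype,
#' over the fits flagged rhythmic; arrhythmic fits are excluded from
#' the statistics but reported in an attrition column.
#'
#' @param fits data.frame from [fit_rhythms()].
#' @param genotype Character vector (one entry per fit row) assigning
#'   each trace to a group, or the name of a column in `fits`.
#' @return data.frame with one row per genotype: `genotype`, `n`
#'   (rhythmic fits), `n_arrhythmic`, `period_mean`, `period_sem`,
#'   `amplitude_mean`, `amplitude_sem`, `rae_mean`, `rae_sem`,
#'   `sem_defined` (FALSE when n < 2; SEMs then reported as 0).
#' @export
summarize_fits <- function(fits, genotype) {
  if (length(genotype) == 1 && genotype %in% names(fits))
    genotype <- fits[[genotype]]
  stopifnot(length(genotype) == nrow(fits))
  sem <- function(x) if (length(x) >= 2)
    stats::sd(x) / sqrt(length(x)) else 0
  rows <- lapply(unique(genotype), function(g) {
    sub <- fits[genotype == g, , drop = FALSE]
    r <- sub[sub$rhythmic %in% TRUE, , drop = FALSE]
    n <- nrow(r)
    data.frame(genotype = g, n = n, n_arrhythmic = nrow(sub) - n,
               period_mean = if (n) mean(r$period) else NA_real_,
               period_sem = if (n) sem(r$period) else NA_real_,
               amplitude_mean = if (n) mean(r$amplitude) else NA_real_,
               amplitude_sem = if (n) sem(r$amplitude) else NA_real_,
               rae_mean = if (n) mean(r$rae) else NA_real_,
               rae_sem = if (n) sem(r$rae) else NA_real_,
               sem_defined = n >= 2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
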
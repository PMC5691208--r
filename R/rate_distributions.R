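#' Lognormal-like firing-rate distribution
#'
#' Builds the firing-rate distribution of the active electrodes in log
#' space: a histogram of `log10(rate)` over 20 equal bins spanning the
#' active band `[log10(0.1), log10(10)]`, with occurrences normalized by
#' the total electrode count of the array (4096 for the default geometry),
#' so the histogram sums to `n_active / n_electrodes`. A Gaussian is fitted
#' to the raw log10 rates (mean and SD, bin-free) when at least
#' `min_fit_n` electrodes are active; otherwise the fit is flagged
#' unavailable.
#'
#' @param a A [compute_activity()] result, or a numeric vector of
#'   per-electrode rates in Hz (the active filter is then applied here and
#'   occurrences are normalized by `n_electrodes_total`).
#' @param n_bins Histogram bin count (default 20).
#' @param min_fit_n Minimum active electrodes for fitting (default 10).
#' @param n_electrodes_total Array size used to normalize occurrences when
#'   `a` is a plain rate vector (default 4096).
#' @return An object of class `rate_distribution`: `log10_rates`,
#'   `bin_centers`, `occurrence`, `fit_mu`, `fit_sigma`, `fit_available`,
#'   `n_active`.
#' @export
build_rate_distribution <- function(a, n_bins = 20L, min_fit_n = 10L,
                                    n_electrodes_total = 4096L) {
  if (inherits(a, "activity_result")) {
    l <- log10(a$rate_hz[a$active])
    n_total <- n_electrodes(a$geometry)
  } else if (is.numeric(a)) {
    rates <- a[a >= 0.1 & a <= 10]
    l <- log10(rates)
    n_total <- n_electrodes_total
  } else {
    stop("a must be an activity_result or a numeric rate vector")
  }
  breaks <- seq(log10(0.1), log10(10), length.out = n_bins + 1L)
  h <- graphics::hist(l, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  fit_ok <- length(l) >= min_fit_n
  structure(list(
    log10_rates = l,
    bin_centers = h$mids,
    occurrence = h$counts / n_total,
    fit_mu = if (fit_ok) mean(l) else NA_real_,
    fit_sigma = if (fit_ok) stats::sd(l) else NA_real_,
    fit_available = fit_ok,
    n_active = length(l)),
    class = "rate_distribution")
}

#' @export
print.rate_distribution <- function(x, ...) {
  if (x$fit_available) {
    cat(sprintf(
      "Rate distribution: %d active electrodes, log10-rate fit mu = %.4g, sigma = %.4g\n",
      x$n_active, x$fit_mu, x$fit_sigma))
  } else {
    cat(sprintf(
      "Rate distribution: %d active electrodes (too few for a fit)\n",
      x$n_active))
  }
  invisible(x)
}

#' Shift between two firing-rate distributions
#'
#' Difference of fitted log10-rate means, `d2 - d1`: negative values mean
#' `d2` is shifted toward lower frequencies (leftward), positive toward
#' higher.
#'
#' @param d1,d2 [build_rate_distribution()] results with available fits.
#' @return Shift in log10 Hz.
#' @export
distribution_shift <- function(d1, d2) {
  stopifnot(inherits(d1, "rate_distribution"),
            inherits(d2, "rate_distribution"))
  if (!d1$fit_available || !d2$fit_available) {
    stop("both distributions must have an available fit")
  }
  d2$fit_mu - d1$fit_mu
}
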
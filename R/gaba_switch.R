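# piecewise-linear crossing of two series sampled on a shared grid:
# smallest t with kc(t) - nk(t) >= 0, NA if the difference stays negative
crossing_div_linear <- function(divs, nk, kc) {
  d <- kc - nk
  if (d[1] >= 0) return(divs[1])
  for (i in seq_len(length(d) - 1L)) {
    if (d[i + 1L] >= 0) {
      # sign change on [i, i+1]: linear interpolation of the difference
      return(divs[i] + (0 - d[i]) * (divs[i + 1L] - divs[i]) /
               (d[i + 1L] - d[i]))
    }
  }
  NA_real_
}

#' Estimate the GABA-polarity switch from expression trajectories
#'
#' The switch is located where the rising KCC2 trajectory crosses the
#' falling NKCC1 trajectory. Both series of means are interpolated
#' piecewise-linearly between the sampled DIVs and the estimate is the
#' smallest DIV at which `KCC2 - NKCC1 >= 0`. If KCC2 already matches or
#' exceeds NKCC1 at the first sampled DIV the crossing is reported there;
#' if KCC2 stays below NKCC1 throughout, no crossing is reported
#' (`crossing_div = NA`).
#'
#' @param nkcc1,kcc2 [expression_series()] on the same DIV grid, with at
#'   least 2 points each.
#' @return An object of class `switch_estimate`: `crossing_div` (day or
#'   `NA`), `method = "linear"`, `genotype`, `divs`.
#' @export
estimate_switch <- function(nkcc1, kcc2) {
  stopifnot(inherits(nkcc1, "expression_series"),
            inherits(kcc2, "expression_series"))
  if (nkcc1$transporter != "NKCC1" || kcc2$transporter != "KCC2") {
    stop("series must be (NKCC1, KCC2) in that order")
  }
  if (nrow(nkcc1$points) < 2L ||
      !identical(nkcc1$points$div, kcc2$points$div)) {
    stop("series must share one DIV grid with >= 2 points")
  }
  divs <- nkcc1$points$div
  structure(list(
    crossing_div = crossing_div_linear(divs, nkcc1$points$mean_pct,
                                       kcc2$points$mean_pct),
    method = "linear", genotype = nkcc1$genotype, divs = divs,
    ci_low = NA_real_, ci_high = NA_real_, n_boot = 0L,
    frac_no_crossing = NA_real_, seed = NA_integer_),
    class = "switch_estimate")
}

#' Bootstrap confidence interval for the switch estimate
#'
#' Parametric bootstrap from the published summary statistics: every
#' sampled mean is redrawn as `Normal(mean, sem)` and the piecewise-linear
#' crossing recomputed per replicate. The interval is the 2.5-97.5
#' percentile range of the replicates with a defined crossing; the
#' fraction of replicates without a crossing is reported alongside.
#'
#' @param nkcc1,kcc2 [expression_series()] on the same DIV grid; every
#'   point needs an SEM.
#' @param n_boot Number of replicates (>= 100).
#' @param seed Integer seed; the bootstrap is fully reproducible.
#' @param conf Confidence level (default 0.95).
#' @return A `switch_estimate` with `ci_low`, `ci_high`, `n_boot`,
#'   `frac_no_crossing` and `seed` filled in; `crossing_div` is the
#'   point estimate from the unperturbed means.
#' @export
bootstrap_switch <- function(nkcc1, kcc2, n_boot = 2000L, seed = 1L,
                             conf = 0.95) {
  if (n_boot < 100L) stop("n_boot must be >= 100")
  est <- estimate_switch(nkcc1, kcc2)
  divs <- nkcc1$points$div
  nk <- nkcc1$points$mean_pct; nk_sem <- nkcc1$points$sem_pct
  kc <- kcc2$points$mean_pct;  kc_sem <- kcc2$points$sem_pct
  set.seed(derive_seed(seed, 0L))
  k <- length(divs)
  nk_rep <- matrix(stats::rnorm(n_boot * k, rep(nk, each = n_boot),
                                rep(nk_sem, each = n_boot)), ncol = k)
  kc_rep <- matrix(stats::rnorm(n_boot * k, rep(kc, each = n_boot),
                                rep(kc_sem, each = n_boot)), ncol = k)
  cross <- vapply(seq_len(n_boot), function(b) {
    crossing_div_linear(divs, nk_rep[b, ], kc_rep[b, ])
  }, numeric(1))
  defined <- cross[!is.na(cross)]
  alpha <- (1 - conf) / 2
  if (length(defined)) {
    qs <- stats::quantile(defined, c(alpha, 1 - alpha), names = FALSE)
    est$ci_low <- qs[1]
    est$ci_high <- qs[2]
  }
  est$n_boot <- as.integer(n_boot)
  est$frac_no_crossing <- mean(is.na(cross))
  est$seed <- as.integer(seed)
  est
}

#' @export
print.switch_estimate <- function(x, ...) {
  if (is.na(x$crossing_div)) {
    cat(sprintf("GABA-polarity switch (%s): no crossing within DIVs %g-%g\n",
                x$genotype, min(x$divs), max(x$divs)))
  } else {
    cat(sprintf("GABA-polarity switch (%s): %.4g DIV", x$genotype,
                x$crossing_div))
    if (!is.na(x$ci_low)) {
      cat(sprintf(" (95%% CI %.4g-%.4g, %d bootstrap replicates)",
                  x$ci_low, x$ci_high, x$n_boot))
    }
    cat("\n")
  }
  invisible(x)
}

#' Printed cotransporter expression fixture
#'
#' Path of the packaged CSV holding the published NKCC1/KCC2 mean +/- SEM
#' expression values for the three genotypes at 8, 16 and 26 DIV, with the
#' 8-DIV reference for WT set to 100% for both transporters.
#'
#' @return File path of the packaged CSV.
#' @export
expression_fixture_path <- function() {
  system.file("extdata", "expression_printed.csv", package = "hdmea",
              mustWork = TRUE)
}
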
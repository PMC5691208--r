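#' Active-electrode filtering and mean firing rate
#'
#' Computes per-electrode firing rates (`spikes / duration`), flags active
#' electrodes — those with rates between 0.1 and 10 events/s, bounds
#' inclusive — and the network mean firing rate (MFR) as the mean rate over
#' active electrodes. With no active electrode the MFR is reported as 0.
#'
#' @param s A [spike_train_set()].
#' @return An object of class `activity_result`: `rate_hz` (vector, one per
#'   electrode in index order), `active` (logical mask), `n_active`, `mfr_hz`,
#'   `mfr_map` (n_rows x n_cols matrix with inactive cells set to 0),
#'   `duration_s`, `geometry`.
#' @export
compute_activity <- function(s) {
  stopifnot(inherits(s, "spike_train_set"))
  g <- s$geometry
  rate <- spike_counts(s) / s$duration_s
  active <- rate >= 0.1 & rate <= 10
  mfr <- if (any(active)) mean(rate[active]) else 0
  masked <- ifelse(active, rate, 0)
  structure(list(rate_hz = rate, active = active,
                 n_active = sum(active), mfr_hz = mfr,
                 mfr_map = matrix(masked, nrow = g$n_rows,
                                  ncol = g$n_cols, byrow = TRUE),
                 duration_s = s$duration_s, geometry = g),
            class = "activity_result")
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf("Activity: %d active electrodes, MFR %.4g Hz\n",
              x$n_active, x$mfr_hz))
  invisible(x)
}

#' Firing-rate map over the electrode grid
#'
#' Rate of every electrode arranged on the array grid, without any
#' active-electrode filtering; `map[row + 1, col + 1]` is the rate of
#' electrode `(row, col)` (0-based grid coordinates).
#'
#' @param s A [spike_train_set()].
#' @return Numeric matrix of Hz, `n_rows` x `n_cols`.
#' @export
rate_map <- function(s) {
  stopifnot(inherits(s, "spike_train_set"))
  g <- s$geometry
  matrix(spike_counts(s) / s$duration_s, nrow = g$n_rows, ncol = g$n_cols,
         byrow = TRUE)
}

#' Summarize negative spike amplitudes above a conservative cutoff
#'
#' Mean negative-peak amplitude over spikes whose peak is at least as large
#' in magnitude as the cutoff (amplitude <= cutoff, e.g. peaks beyond
#' -250 uV for the default). With no qualifying spike the mean is `NA` and
#' `n_spikes_used` is 0.
#'
#' @param s A [spike_train_set()].
#' @param cutoff_uV Amplitude cutoff in uV (< 0; default -250).
#' @return An object of class `amplitude_summary`: `mean_negative_peak_uV`,
#'   `n_spikes_used`, `cutoff_uV`.
#' @export
summarize_amplitudes <- function(s, cutoff_uV = -250) {
  stopifnot(inherits(s, "spike_train_set"))
  if (cutoff_uV >= 0) stop("cutoff_uV must be negative")
  amp <- s$spikes$amplitude_uV
  used <- amp <= cutoff_uV
  structure(list(
    mean_negative_peak_uV = if (any(used)) mean(amp[used]) else NA_real_,
    n_spikes_used = sum(used), cutoff_uV = cutoff_uV),
    class = "amplitude_summary")
}

#' @export
print.amplitude_summary <- function(x, ...) {
  if (x$n_spikes_used == 0L) {
    cat(sprintf("Amplitude summary: no spikes beyond %g uV\n", x$cutoff_uV))
  } else {
    cat(sprintf("Amplitude summary: mean %.4g uV over %d spikes (cutoff %g uV)\n",
                x$mean_negative_peak_uV, x$n_spikes_used, x$cutoff_uV))
  }
  invisible(x)
}
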
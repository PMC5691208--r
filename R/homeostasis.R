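#' Normalize raw MFRs to a baseline timepoint
#'
#' Converts a sequence of raw mean firing rates into percent-of-baseline
#' values (baseline = 100), the scale on which homeostatic responses are
#' read out.
#'
#' @param labels Timepoint labels, in chronological order.
#' @param mfr_hz Raw MFR at each timepoint (Hz).
#' @param baseline_label Label of the baseline timepoint (must be present,
#'   with MFR > 0).
#' @return An object of class `mfr_timeline`: data frame `timepoint`,
#'   `mfr_pct`, plus the `baseline_label`.
#' @export
normalize_to_baseline <- function(labels, mfr_hz, baseline_label) {
  stopifnot(length(labels) == length(mfr_hz))
  i <- match(baseline_label, labels)
  if (is.na(i)) stop("baseline label not found: ", baseline_label)
  if (mfr_hz[i] <= 0) stop("baseline MFR must be > 0")
  structure(list(
    timeline = data.frame(timepoint = as.character(labels),
                          mfr_pct = 100 * mfr_hz / mfr_hz[i]),
    baseline_label = baseline_label),
    class = "mfr_timeline")
}

#' Fold change between two percent values
#'
#' Plain ratio `a_pct / b_pct`, the arithmetic used to report, e.g., a
#' "2-fold" MFR reduction between treated and untreated cultures.
#'
#' @param a_pct,b_pct Percent-of-baseline values; `b_pct` must be > 0.
#' @return Unitless fold change.
#' @export
fold_change <- function(a_pct, b_pct) {
  if (any(b_pct == 0)) stop("fold change undefined for zero denominator")
  a_pct / b_pct
}

#' Classify a homeostatic-plasticity trajectory
#'
#' Reads out a perturbation-response trajectory on the percent-of-baseline
#' scale: the early response direction (at `t_response`, default the 2 h
#' point) is `"increase"`/`"decrease"` when the value leaves a +/- 5% dead
#' band around baseline, `"none"` otherwise; the network counts as restored
#' when the late value (at `t_final`, default 48 h) is within
#' `tolerance_pct` of baseline.
#'
#' @param timeline An `mfr_timeline` from [normalize_to_baseline()], or a
#'   data frame with columns `timepoint`, `mfr_pct`.
#' @param t_response,t_final Labels of the early-response and final
#'   timepoints.
#' @param tolerance_pct Restoration tolerance, percent of baseline
#'   (default 12).
#' @param deadband_pct Direction dead band (default 5).
#' @return An object of class `homeostasis_verdict`: `response_direction`
#'   (`"increase"`, `"decrease"` or `"none"`), `restored` (logical),
#'   `mfr_response_pct`, `mfr_final_pct`, `tolerance_pct`.
#' @export
classify_homeostasis <- function(timeline, t_response = "2h",
                                 t_final = "48h", tolerance_pct = 12,
                                 deadband_pct = 5) {
  tab <- if (inherits(timeline, "mfr_timeline")) timeline$timeline else timeline
  stopifnot(all(c("timepoint", "mfr_pct") %in% names(tab)))
  v_resp <- tab$mfr_pct[match(t_response, tab$timepoint)]
  v_fin <- tab$mfr_pct[match(t_final, tab$timepoint)]
  if (is.na(v_resp) || is.na(v_fin)) {
    stop("timeline must contain timepoints '", t_response, "' and '",
         t_final, "'")
  }
  direction <- if (v_resp > 100 + deadband_pct) {
    "increase"
  } else if (v_resp < 100 - deadband_pct) {
    "decrease"
  } else {
    "none"
  }
  structure(list(response_direction = direction,
                 restored = abs(v_fin - 100) <= tolerance_pct,
                 mfr_response_pct = v_resp, mfr_final_pct = v_fin,
                 tolerance_pct = tolerance_pct),
            class = "homeostasis_verdict")
}

#' @export
print.homeostasis_verdict <- function(x, ...) {
  cat(sprintf("Homeostasis: %s at the response point (%.4g%%), %s at the final point (%.4g%%, tolerance +/-%g%%)\n",
              x$response_direction, x$mfr_response_pct,
              if (x$restored) "restored" else "not restored",
              x$mfr_final_pct, x$tolerance_pct))
  invisible(x)
}
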
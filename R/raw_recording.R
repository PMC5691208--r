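#' Raw extracellular recording
#'
#' Per-electrode voltage traces in microvolts, sampled at a common rate.
#' Traces are held in a named list keyed by 0-based electrode index as a
#' character string; electrodes without a trace are treated as absent (not
#' recorded), which keeps small simulated subsets of a large array cheap.
#'
#' @param traces Named list of numeric vectors (uV); names are 0-based
#'   electrode indices. All traces must have equal length.
#' @param sampling_rate_hz Sampling rate in Hz (default 7800, the full-frame
#'   rate of the 4096-electrode chip).
#' @param geometry An [array_geometry()].
#' @return An object of class `raw_recording` with elements `traces`,
#'   `sampling_rate_hz`, `geometry`, `n_samples`, `duration_s`.
#' @export
raw_recording <- function(traces, sampling_rate_hz = 7800,
                          geometry = array_geometry()) {
  if (!is.list(traces) || is.null(names(traces))) {
    stop("traces must be a named list keyed by electrode index")
  }
  lens <- lengths(traces)
  if (length(lens) && length(unique(lens)) != 1L) {
    stop("all traces must have equal length")
  }
  idx <- suppressWarnings(as.integer(names(traces)))
  if (any(is.na(idx)) || any(idx < 0L | idx >= n_electrodes(geometry))) {
    stop("trace names must be valid 0-based electrode indices")
  }
  n_samples <- if (length(lens)) lens[[1]] else 0L
  structure(
    list(traces = traces, sampling_rate_hz = sampling_rate_hz,
         geometry = geometry, n_samples = n_samples,
         duration_s = n_samples / sampling_rate_hz),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("Raw recording: %d traces, %.6g s at %g Hz\n",
              length(x$traces), x$duration_s, x$sampling_rate_hz))
  invisible(x)
}
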
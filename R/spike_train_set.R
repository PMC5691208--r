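#' Spike train set
#'
#' The central container of the pipeline: spike times and negative-peak
#' amplitudes for every electrode of an array, plus the recording duration
#' and optional culture metadata (genotype, DIV, condition).
#'
#' Times are stored in seconds, amplitudes in microvolts with their sign
#' (extracellular spikes are negative-going, so amplitudes are <= 0).
#'
#' @param spikes Data frame with columns `electrode` (0-based index),
#'   `time_s` and `amplitude_uV`. May have zero rows.
#' @param geometry An [array_geometry()].
#' @param duration_s Recording duration in seconds.
#' @param metadata Optional named list (e.g. `genotype`, `div`, `condition`).
#' @return An object of class `spike_train_set` with elements `spikes`
#'   (sorted by electrode, then time), `geometry`, `duration_s`, `metadata`.
#' @export
spike_train_set <- function(spikes, geometry = array_geometry(),
                            duration_s, metadata = list()) {
  if (missing(duration_s) || !is.numeric(duration_s) || duration_s <= 0) {
    stop("duration_s must be a positive number")
  }
  needed <- c("electrode", "time_s", "amplitude_uV")
  if (!all(needed %in% names(spikes))) {
    stop("spikes must have columns: ", paste(needed, collapse = ", "))
  }
  spikes <- as.data.frame(spikes)[, needed]
  spikes$electrode <- as.integer(spikes$electrode)
  spikes <- spikes[order(spikes$electrode, spikes$time_s), , drop = FALSE]
  rownames(spikes) <- NULL
  obj <- structure(
    list(spikes = spikes, geometry = geometry,
         duration_s = as.numeric(duration_s), metadata = metadata),
    class = "spike_train_set"
  )
  validate_spike_train_set(obj)
  obj
}

#' Validate a spike train set
#'
#' Checks the container invariants: electrode indices within the array,
#' times within `[0, duration]` and strictly increasing per electrode,
#' amplitudes non-positive.
#'
#' @param s A `spike_train_set`.
#' @return `s`, invisibly; errors otherwise.
#' @export
validate_spike_train_set <- function(s) {
  stopifnot(inherits(s, "spike_train_set"))
  sp <- s$spikes
  n_el <- n_electrodes(s$geometry)
  if (nrow(sp) == 0L) return(invisible(s))
  if (any(sp$electrode < 0L | sp$electrode >= n_el)) {
    stop("electrode index out of range [0, ", n_el - 1L, "]")
  }
  if (any(sp$time_s < 0 | sp$time_s > s$duration_s)) {
    stop("spike times must lie in [0, duration]")
  }
  if (any(sp$amplitude_uV > 0)) {
    stop("amplitudes must be <= 0 (negative-going peaks)")
  }
  # strictly increasing within electrode: after electrode/time sort, a
  # non-positive time step inside one electrode means a duplicate
  same <- diff(sp$electrode) == 0L
  if (any(same & diff(sp$time_s) <= 0)) {
    stop("spike times must be strictly increasing per electrode")
  }
  invisible(s)
}

#' Per-electrode spike counts
#' @param s A `spike_train_set`.
#' @return Integer vector of length `n_electrodes(s$geometry)`, one count per
#'   electrode in index order (0-based electrode i at position i + 1).
#' @export
spike_counts <- function(s) {
  stopifnot(inherits(s, "spike_train_set"))
  tabulate(s$spikes$electrode + 1L, nbins = n_electrodes(s$geometry))
}

#' Spike times of one electrode
#' @param s A `spike_train_set`.
#' @param electrode 0-based electrode index.
#' @return Numeric vector of sorted spike times (seconds).
#' @export
spike_times <- function(s, electrode) {
  s$spikes$time_s[s$spikes$electrode == electrode]
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf(
    "Spike train set: %d spikes on %d/%d electrodes, %.6g s\n",
    nrow(x$spikes), length(unique(x$spikes$electrode)),
    n_electrodes(x$geometry), x$duration_s))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a spike table
#'
#' Reads a CSV spike table with header `electrode,time_s,amplitude_uV` into
#' a [spike_train_set()]. Rows are sorted per electrode; out-of-range
#' electrodes or times, positive amplitudes and duplicate times on one
#' electrode are rejected.
#'
#' @param path Path to the CSV file.
#' @param geometry An [array_geometry()].
#' @param duration_s Recording duration in seconds.
#' @param metadata Optional metadata list, as for [spike_train_set()].
#' @return A `spike_train_set`.
#' @export
read_spike_table <- function(path, geometry = array_geometry(), duration_s,
                             metadata = list()) {
  tab <- utils::read.csv(path, colClasses = c(electrode = "integer",
                                              time_s = "numeric",
                                              amplitude_uV = "numeric"))
  needed <- c("electrode", "time_s", "amplitude_uV")
  if (!all(needed %in% names(tab))) {
    stop("spike table must have columns: ", paste(needed, collapse = ", "))
  }
  spike_train_set(tab, geometry = geometry, duration_s = duration_s,
                  metadata = metadata)
}

#' Write a spike table
#'
#' Writes the spikes of a [spike_train_set()] as CSV with header
#' `electrode,time_s,amplitude_uV`. Values are written with enough digits
#' that [read_spike_table()] round-trips the set exactly.
#'
#' @param s A `spike_train_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(s, path) {
  validate_spike_train_set(s)
  sp <- s$spikes
  out <- data.frame(electrode = sp$electrode,
                    time_s = sprintf("%.17g", sp$time_s),
                    amplitude_uV = sprintf("%.17g", sp$amplitude_uV))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
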
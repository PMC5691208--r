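#' Spike detection parameters
#'
#' Settings of the differential-threshold (precise-timing style) spike
#' detector. The detection threshold is `threshold_multiplier` times the
#' per-electrode noise SD; a candidate negative peak is accepted when the
#' peak-to-peak excursion between it and the largest maximum within
#' `peak_lifetime_ms` exceeds that threshold.
#'
#' @param threshold_multiplier Threshold in units of the noise SD
#'   (default 9).
#' @param peak_lifetime_ms Half-window (ms) in which the matching positive
#'   excursion is sought (default 2).
#' @param refractory_ms Minimum separation (ms) between accepted spikes on
#'   one electrode; the larger-magnitude peak wins (default 1).
#' @param noise_estimator `"mad"` (median absolute deviation scaled to the
#'   Gaussian SD; robust to the spikes themselves) or `"sd"` (sample SD).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(threshold_multiplier = 9, peak_lifetime_ms = 2,
                             refractory_ms = 1,
                             noise_estimator = c("mad", "sd")) {
  stopifnot(threshold_multiplier > 0, peak_lifetime_ms > 0,
            refractory_ms >= 0)
  structure(list(threshold_multiplier = threshold_multiplier,
                 peak_lifetime_ms = peak_lifetime_ms,
                 refractory_ms = refractory_ms,
                 noise_estimator = match.arg(noise_estimator)),
            class = "detection_params")
}

#' Estimate the noise SD of a voltage trace
#'
#' With `estimator = "mad"` returns `median(|x - median(x)|) / 0.6745`,
#' the median absolute deviation scaled to equal the SD for Gaussian noise;
#' this is robust against the spikes riding on the noise. With
#' `estimator = "sd"` returns the sample standard deviation.
#'
#' @param trace Numeric voltage trace (uV), at least 1000 samples.
#' @param estimator `"mad"` or `"sd"`.
#' @return Estimated noise SD in uV.
#' @export
estimate_noise_sd <- function(trace, estimator = c("mad", "sd")) {
  estimator <- match.arg(estimator)
  if (length(trace) < 1000L) {
    stop("trace too short for noise estimation (need >= 1000 samples)")
  }
  if (estimator == "mad") {
    stats::median(abs(trace - stats::median(trace))) / 0.6745
  } else {
    stats::sd(trace)
  }
}

# detect spikes in a single trace; returns data.frame(sample, amplitude_uV)
detect_spikes_trace <- function(tr, sampling_rate_hz, params) {
  noise <- estimate_noise_sd(tr, params$noise_estimator)
  thr <- params$threshold_multiplier * noise
  n <- length(tr)
  # local negative minima (plateaus resolved to their first sample)
  d <- diff(tr)
  mins <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  if (!length(mins)) return(data.frame(sample = integer(0),
                                       amplitude_uV = numeric(0)))
  w <- max(1L, as.integer(round(params$peak_lifetime_ms / 1000 *
                                  sampling_rate_hz)))
  # running max of the trace over +/- w samples; -Inf padding restricts
  # edge windows to in-range samples
  padded <- c(rep(-Inf, w), tr, rep(-Inf, w))
  rmax <- zoo::rollmax(padded, k = 2L * w + 1L, align = "center")
  cand <- mins[rmax[mins] - tr[mins] > thr]
  if (!length(cand)) return(data.frame(sample = integer(0),
                                       amplitude_uV = numeric(0)))
  # refractory suppression: keep the larger-magnitude of two peaks closer
  # than the refractory period
  refr <- params$refractory_ms / 1000 * sampling_rate_hz
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refr) {
      keep <- c(keep, i)
      last <- i
    } else if (tr[i] < tr[keep[length(keep)]]) {
      keep[length(keep)] <- i
      last <- i
    }
  }
  data.frame(sample = keep, amplitude_uV = tr[keep])
}

#' Detect spikes in a raw recording
#'
#' Differential-threshold detection per electrode: the threshold is
#' `threshold_multiplier` times the electrode's estimated noise SD; a spike
#' is emitted at each local negative minimum whose peak-to-peak excursion
#' to the largest trace value within `peak_lifetime_ms` exceeds the
#' threshold. The timestamp is the negative-peak sample and the amplitude
#' the trace value there. Detections within the refractory period of the
#' previous accepted spike are suppressed, keeping the larger-magnitude
#' peak.
#'
#' @param rec A [raw_recording()].
#' @param params A [detection_params()].
#' @param metadata Optional metadata for the returned set.
#' @return A [spike_train_set()].
#' @export
detect_spikes <- function(rec, params = detection_params(),
                          metadata = list()) {
  stopifnot(inherits(rec, "raw_recording"),
            inherits(params, "detection_params"))
  fs <- rec$sampling_rate_hz
  dfs <- lapply(names(rec$traces), function(nm) {
    det <- detect_spikes_trace(rec$traces[[nm]], fs, params)
    if (nrow(det) == 0L) return(NULL)
    data.frame(electrode = as.integer(nm),
               time_s = (det$sample - 1L) / fs,
               amplitude_uV = pmin(det$amplitude_uV, 0))
  })
  spikes <- do.call(rbind, c(dfs, list(
    data.frame(electrode = integer(0), time_s = numeric(0),
               amplitude_uV = numeric(0)))))
  spike_train_set(spikes, geometry = rec$geometry,
                  duration_s = rec$duration_s, metadata = metadata)
}
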
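#' Single-electrode burst detection and mean bursting rate
#'
#' A burst is a maximal run of at least five consecutive spikes on one
#' electrode in which every inter-spike interval is strictly below 100 ms.
#' The mean bursting rate (MBR) is the mean over active electrodes (rates
#' between 0.1 and 10 Hz, inclusive) of bursts per minute; active
#' electrodes without bursts contribute 0.
#'
#' @param s A [spike_train_set()].
#' @param max_isi_s In-burst ISI bound in seconds (strict; default 0.1).
#' @param min_spikes Minimum spikes per burst (default 5).
#' @return A list: `bursts` (data frame `electrode`, `start_s`, `end_s`,
#'   `n_spikes`) and `mbr_per_min` (mean bursting rate).
#' @export
detect_bursts <- function(s, max_isi_s = 0.1, min_spikes = 5L) {
  stopifnot(inherits(s, "spike_train_set"))
  act <- compute_activity(s)
  per_el <- split(s$spikes$time_s, s$spikes$electrode)
  dfs <- lapply(names(per_el), function(nm) {
    t <- per_el[[nm]]
    if (length(t) < min_spikes) return(NULL)
    ok <- diff(t) < max_isi_s
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- r$values & r$lengths >= (min_spikes - 1L)
    if (!any(sel)) return(NULL)
    # run of L TRUE ISIs covers L + 1 spikes from index starts to ends + 1
    data.frame(electrode = as.integer(nm),
               start_s = t[starts[sel]],
               end_s = t[ends[sel] + 1L],
               n_spikes = r$lengths[sel] + 1L)
  })
  bursts <- do.call(rbind, c(dfs, list(
    data.frame(electrode = integer(0), start_s = numeric(0),
               end_s = numeric(0), n_spikes = integer(0)))))
  rownames(bursts) <- NULL
  mbr <- if (act$n_active > 0) {
    counts <- tabulate(bursts$electrode + 1L,
                       nbins = n_electrodes(s$geometry))
    mean(counts[act$active]) / (s$duration_s / 60)
  } else {
    0
  }
  list(bursts = bursts, mbr_per_min = mbr)
}

#' Network-burst detection
#'
#' Time is partitioned into contiguous bins (default 15 ms, aligned to
#' t = 0). Per bin, participation is the number of distinct active
#' electrodes firing at least one spike. Bins whose participation strictly
#' exceeds `threshold_frac` times the number of active electrodes are event
#' bins; event bins separated by less than `window_ms` merge into a single
#' network burst (NB). An NB spans from the leading edge of its first event
#' bin to the trailing edge of its last; its peak participation is the
#' maximum over its bins.
#'
#' @param s A [spike_train_set()].
#' @param bin_ms Bin width in ms (default 15).
#' @param window_ms Merge horizon between event bins in ms (default 150).
#' @param threshold_frac Participation threshold as a fraction of active
#'   electrodes (default 0.15).
#' @return Data frame with one row per NB: `start_s`, `end_s`,
#'   `peak_participation`, `n_bins`.
#' @export
detect_network_bursts <- function(s, bin_ms = 15, window_ms = 150,
                                  threshold_frac = 0.15) {
  stopifnot(inherits(s, "spike_train_set"), bin_ms > 0, window_ms >= 0,
            threshold_frac >= 0)
  act <- compute_activity(s)
  if (act$n_active < 1L) stop("network-burst detection needs >= 1 active electrode")
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      peak_participation = integer(0), n_bins = integer(0))
  active_ids <- which(act$active) - 1L
  sel <- s$spikes$electrode %in% active_ids
  if (!any(sel)) return(empty)
  bin_s <- bin_ms / 1000
  bin_idx <- floor(s$spikes$time_s[sel] / bin_s)
  # distinct (bin, electrode) pairs -> per-bin participation counts
  pairs <- unique(data.frame(bin = bin_idx, el = s$spikes$electrode[sel]))
  part <- table(pairs$bin)
  thr <- threshold_frac * act$n_active
  ev_bins <- as.numeric(names(part))[as.numeric(part) > thr]
  if (!length(ev_bins)) return(empty)
  ev_bins <- sort(ev_bins)
  ev_part <- as.numeric(part)[match(ev_bins, as.numeric(names(part)))]
  # merge event bins whose leading edges are < window_ms + bin_ms apart,
  # i.e. gap between consecutive event bins < window_ms
  gap_s <- (diff(ev_bins) - 1) * bin_s
  grp <- cumsum(c(1, gap_s >= window_ms / 1000))
  out <- lapply(split(seq_along(ev_bins), grp), function(ii) {
    data.frame(start_s = ev_bins[ii[1]] * bin_s,
               end_s = (ev_bins[ii[length(ii)]] + 1) * bin_s,
               peak_participation = as.integer(max(ev_part[ii])),
               n_bins = length(ii))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Inter-burst-interval distribution
#'
#' Intervals between successive event onsets (start-to-start), smoothed in
#' log time: a Gaussian kernel density of `log10(IBI)` with bandwidth equal
#' to 5% of the log10-IBI range, evaluated on a 256-point grid spanning the
#' data plus three bandwidths each side, and renormalized so the trapezoid
#' integral over the grid is 1.
#'
#' @param starts Numeric vector of event onset times in seconds (bursts or
#'   network bursts), at least 2.
#' @param n_grid Number of grid points (default 256).
#' @return An object of class `ibi_distribution`: `ibis_s`, `log10_grid`,
#'   `density`, `bandwidth`.
#' @export
ibi_distribution <- function(starts, n_grid = 256L) {
  if (length(starts) < 2L) stop("need at least 2 events for an IBI distribution")
  starts <- sort(starts)
  ibis <- diff(starts)
  if (any(ibis <= 0)) stop("event onsets must be distinct")
  l <- log10(ibis)
  bw <- 0.05 * (max(l) - min(l))
  if (bw == 0) bw <- 1e-3  # all IBIs identical: keep the kernel proper
  grid <- seq(min(l) - 3 * bw, max(l) + 3 * bw, length.out = n_grid)
  # exact kernel sum (no FFT binning): event counts are small enough
  dens <- vapply(grid, function(x0) {
    mean(stats::dnorm((x0 - l) / bw)) / bw
  }, numeric(1))
  integral <- sum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid))
  structure(list(ibis_s = ibis, log10_grid = grid, density = dens / integral,
                 bandwidth = bw),
            class = "ibi_distribution")
}

#' @export
print.ibi_distribution <- function(x, ...) {
  cat(sprintf("IBI distribution: %d intervals, median %.4g s, bandwidth %.3g (log10 s)\n",
              length(x$ibis_s), stats::median(x$ibis_s), x$bandwidth))
  invisible(x)
}
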
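# Independent oracles and small fixture builders shared across tests.

# Brute-force burst scan: walks the train spike by spike, keeping runs in
# which every ISI stays strictly below max_isi, and records maximal runs of
# at least min_spikes. Deliberately written as a plain loop, independent of
# the rle-based implementation in the package.
oracle_bursts <- function(t, max_isi = 0.1, min_spikes = 5L) {
  starts <- ends <- numeric(0)
  ns <- integer(0)
  n <- length(t)
  run_start <- 1L
  flush <- function(from, to) {
    if (to - from + 1L >= min_spikes) {
      starts <<- c(starts, t[from])
      ends <<- c(ends, t[to])
      ns <<- c(ns, to - from + 1L)
    }
  }
  if (n > 0L) {
    for (i in seq_len(n)[-1]) {
      if (t[i] - t[i - 1L] >= max_isi) {
        flush(run_start, i - 1L)
        run_start <- i
      }
    }
    flush(run_start, n)
  }
  data.frame(start_s = starts, end_s = ends, n_spikes = ns)
}

# Random spike train with mixed tonic and bursty structure, for
# property-testing the burst scanner against the oracle.
random_train <- function(n_spikes, duration = 60, p_bursty = 0.4) {
  if (stats::runif(1) < p_bursty) {
    # clumps of short ISIs interleaved with long gaps
    isis <- ifelse(stats::runif(n_spikes) < 0.6,
                   stats::runif(n_spikes, 0.005, 0.12),
                   stats::rexp(n_spikes, 2))
    t <- cumsum(isis)
    t[t <= duration]
  } else {
    sort(stats::runif(n_spikes, 0, duration))
  }
}

# Greedy one-to-one matching of detected to planted spike times within a
# tolerance; returns precision and recall.
match_spikes <- function(detected, planted, tol = 0.001) {
  used <- rep(FALSE, length(detected))
  hits <- 0L
  for (tp in planted) {
    d <- abs(detected - tp)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      used[j] <- TRUE
      hits <- hits + 1L
    }
  }
  list(precision = if (length(detected)) hits / length(detected) else NA,
       recall = if (length(planted)) hits / length(planted) else NA)
}

# Pure-noise recording on one electrode.
noise_recording <- function(duration_s, noise_sd = 5, fs = 7800, seed = 1) {
  set.seed(seed)
  raw_recording(list("0" = stats::rnorm(round(duration_s * fs), 0, noise_sd)),
                sampling_rate_hz = fs, geometry = array_geometry(1, 1))
}

# Spike set with synchronous events planted at known, well-separated times:
# n_events network events on a regular grid, each recruiting half of the
# electrodes, on top of sparse asynchronous background firing.
synchronous_set <- function(seed, n_electrodes = 100L, duration = 600,
                            n_events = 30L, jitter_sd = 0.005) {
  set.seed(seed)
  geom <- array_geometry(10, 10)
  ev_times <- seq(10, duration - 10, length.out = n_events)
  dfs <- lapply(seq_len(n_electrodes) - 1L, function(e) {
    t_bg <- sort(stats::runif(stats::rpois(1, 0.2 * duration), 0, duration))
    recruited <- ev_times[stats::runif(n_events) < 0.5]
    t_ev <- rep(recruited, each = 2) +
      stats::rnorm(2 * length(recruited), 0, jitter_sd)
    t <- sort(unique(c(t_bg, t_ev)))
    t <- t[t >= 0 & t <= duration]
    if (!length(t)) return(NULL)
    data.frame(electrode = e, time_s = t, amplitude_uV = -60)
  })
  list(spikes = spike_train_set(do.call(rbind, dfs), geom, duration),
       event_times = ev_times)
}

printed_expression <- function() read_expression_csv(expression_fixture_path())

printed_timeline <- function() {
  read_timeline_csv(system.file("extdata", "mfr_timeline_printed.csv",
                                package = "hdmea", mustWork = TRUE))
}
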
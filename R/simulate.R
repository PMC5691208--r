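#' @keywords internal
#' Deterministic substream seed: one global seed expands to per-electrode
#' (and per-stage) seeds so parallel or partial re-evaluation reproduces
#' the same draws. Kept below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647) * 48271 %% 2147483647 +
               7919 * k) %% 2147483647L
}

#' Network activity preset
#'
#' Generative parameters for a synthetic developing network on the array:
#' heterogeneous tonic firing with lognormal rates, network-burst (NB)
#' events recruiting a random electrode subset, and a fraction of
#' electrodes emitting intrinsic single-channel bursts.
#'
#' @param n_active Number of spiking electrodes (0 to array size).
#' @param rate_mu_log10,rate_sigma_log10 Mean and SD of per-electrode
#'   log10 firing rate (log10 Hz); realized rates are clipped to
#'   `[0.01, 20]` Hz.
#' @param nb_rate_per_min NB events per minute (Poisson process, >= 0).
#' @param nb_participation Fraction of active electrodes recruited per NB.
#' @param nb_spikes_per_electrode Mean in-burst spike count per recruited
#'   electrode (Poisson).
#' @param nb_jitter_s SD (s) of the Gaussian jitter of in-burst spikes
#'   around the event time.
#' @param burst_trains_fraction Fraction of active electrodes that also emit
#'   intrinsic bursts of >= 5 spikes at short ISIs.
#' @param seed Integer seed; identical presets yield identical simulations.
#' @return An object of class `network_preset`.
#' @export
network_preset <- function(n_active, rate_mu_log10, rate_sigma_log10,
                           nb_rate_per_min = 0, nb_participation = 0,
                           nb_spikes_per_electrode = 0, nb_jitter_s = 0.01,
                           burst_trains_fraction = 0, seed = 1L) {
  stopifnot(n_active >= 0, rate_sigma_log10 >= 0, nb_rate_per_min >= 0,
            nb_participation >= 0, nb_participation <= 1,
            nb_spikes_per_electrode >= 0, nb_jitter_s >= 0,
            burst_trains_fraction >= 0, burst_trains_fraction <= 1)
  structure(list(n_active = as.integer(n_active),
                 rate_mu_log10 = rate_mu_log10,
                 rate_sigma_log10 = rate_sigma_log10,
                 nb_rate_per_min = nb_rate_per_min,
                 nb_participation = nb_participation,
                 nb_spikes_per_electrode = nb_spikes_per_electrode,
                 nb_jitter_s = nb_jitter_s,
                 burst_trains_fraction = burst_trains_fraction,
                 seed = as.integer(seed)),
            class = "network_preset")
}

#' Packaged genotype-like network presets
#'
#' Loads one of the named presets shipped with the package
#' (`inst/extdata/network_presets.yaml`). The presets encode the
#' qualitative developmental contrasts of the three genotypes: immature
#' mutant networks at 8 DIV lack network bursts (`Lgdel-8div` has
#' `nb_rate_per_min = 0`) while the deletion model is hyper-excitable at
#' 16 DIV (`Lgdel-16div` has a higher mean rate than `WT-16div`).
#'
#' @param name One of `"WT-8div"`, `"WT-16div"`, `"Lgdel-8div"`,
#'   `"Lgdel-16div"`, `"Dgcr8-16div"`.
#' @param seed Seed stored in the returned preset.
#' @return A [network_preset()].
#' @export
network_preset_fixture <- function(name, seed = 1L) {
  path <- system.file("extdata", "network_presets.yaml", package = "hdmea",
                      mustWork = TRUE)
  all <- yaml::read_yaml(path)
  if (!name %in% names(all)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(all), collapse = ", "))
  }
  p <- all[[name]]
  network_preset(n_active = p$n_active, rate_mu_log10 = p$rate_mu_log10,
                 rate_sigma_log10 = p$rate_sigma_log10,
                 nb_rate_per_min = p$nb_rate_per_min,
                 nb_participation = p$nb_participation,
                 nb_spikes_per_electrode = p$nb_spikes_per_electrode,
                 nb_jitter_s = p$nb_jitter_s,
                 burst_trains_fraction = p$burst_trains_fraction,
                 seed = seed)
}

# greedy dead-time thinning: keep a spike only if >= dead_s after the last
# kept spike; each pass drops the first violator of every violation run
enforce_dead_time <- function(t, dead_s = 0.002) {
  repeat {
    if (length(t) < 2L) return(t)
    bad <- which(diff(t) < dead_s) + 1L
    if (!length(bad)) return(t)
    bad <- bad[c(TRUE, diff(bad) > 1L)]
    t <- t[-bad]
  }
}

#' Simulate a developing network recording
#'
#' Generates a ground-truth spike train set: per-electrode tonic firing as
#' homogeneous Poisson processes with electrode-specific rates drawn from a
#' lognormal distribution (`log10 r ~ Normal(mu, sigma)`, clipped to
#' `[0.01, 20]` Hz), network-burst events as a Poisson process in time,
#' each recruiting a binomial subset of active electrodes which add
#' `Poisson(nb_spikes_per_electrode)` spikes jittered
#' `Normal(0, nb_jitter_s)` around the event time, and intrinsic
#' single-channel bursts on a preset fraction of electrodes. A 2 ms dead
#' time removes unphysically short ISIs. Everything is a pure function of
#' (preset, duration, geometry): the preset's seed fixes all draws.
#'
#' @param preset A [network_preset()].
#' @param duration_s Recording duration in seconds (> 0).
#' @param geometry An [array_geometry()].
#' @return A list with elements `spikes` (a [spike_train_set()]) and
#'   `ground_truth` (list: `nb_times` of planted NB event times,
#'   `electrodes` data frame with per-electrode true `rate_hz` and
#'   `bursting` flag, and the `preset`).
#' @export
simulate_network <- function(preset, duration_s, geometry = array_geometry()) {
  stopifnot(inherits(preset, "network_preset"), duration_s > 0)
  n_el <- n_electrodes(geometry)
  if (preset$n_active > n_el) stop("n_active exceeds array size")
  if (preset$n_active == 0L && preset$nb_rate_per_min > 0) {
    stop("nb_rate_per_min > 0 requires at least one active electrode")
  }

  set.seed(derive_seed(preset$seed, 0L))
  active <- sort(sample.int(n_el, preset$n_active) - 1L)
  rates <- 10^stats::rnorm(preset$n_active, preset$rate_mu_log10,
                           preset$rate_sigma_log10)
  rates <- pmin(pmax(rates, 0.01), 20)
  bursting <- stats::runif(preset$n_active) < preset$burst_trains_fraction
  amp_mean <- -(40 + 80 * stats::runif(preset$n_active))

  n_ev <- stats::rpois(1, preset$nb_rate_per_min * duration_s / 60)
  nb_times <- sort(stats::runif(n_ev, 0, duration_s))
  recruited <- matrix(stats::runif(n_ev * max(preset$n_active, 1L)) <
                        preset$nb_participation,
                      nrow = n_ev)

  dfs <- vector("list", preset$n_active)
  for (i in seq_len(preset$n_active)) {
    set.seed(derive_seed(preset$seed, i))
    t_tonic <- stats::runif(stats::rpois(1, rates[i] * duration_s),
                            0, duration_s)
    t_burst <- numeric(0)
    if (bursting[i]) {
      # intrinsic bursts at 2/min, 5+ spikes, 20-80 ms ISIs
      n_b <- stats::rpois(1, 2 * duration_s / 60)
      for (b in seq_len(n_b)) {
        n_spk <- 5L + stats::rpois(1, 1)
        isis <- stats::runif(n_spk - 1L, 0.02, 0.08)
        t_burst <- c(t_burst,
                     stats::runif(1, 0, duration_s) + c(0, cumsum(isis)))
      }
    }
    t_nb <- numeric(0)
    if (n_ev > 0L) {
      for (ev in which(recruited[, i])) {
        k <- stats::rpois(1, preset$nb_spikes_per_electrode)
        t_nb <- c(t_nb, nb_times[ev] +
                    stats::rnorm(k, 0, preset$nb_jitter_s))
      }
    }
    t_all <- sort(c(t_tonic, t_burst, t_nb))
    t_all <- t_all[t_all >= 0 & t_all <= duration_s]
    t_all <- enforce_dead_time(t_all)
    n_sp <- length(t_all)
    if (n_sp == 0L) next
    amp <- -abs(amp_mean[i] * (1 + 0.15 * stats::rnorm(n_sp)))
    dfs[[i]] <- data.frame(electrode = active[i], time_s = t_all,
                           amplitude_uV = amp)
  }
  spikes <- do.call(rbind, c(dfs, list(
    data.frame(electrode = integer(0), time_s = numeric(0),
               amplitude_uV = numeric(0)))))
  s <- spike_train_set(spikes, geometry = geometry, duration_s = duration_s)
  list(spikes = s,
       ground_truth = list(
         nb_times = nb_times,
         electrodes = data.frame(electrode = active, rate_hz = rates,
                                 bursting = bursting),
         preset = preset))
}

#' Biphasic extracellular spike template
#'
#' A stereotyped extracellular action-potential waveform: a dominant
#' negative lobe followed by a smaller positive after-potential. The
#' waveform starts and ends at 0 and its minimum equals `peak_amplitude_uV`.
#'
#' @param peak_amplitude_uV Negative peak amplitude (uV, < 0).
#' @param width_ms Total template width in milliseconds.
#' @param sampling_rate_hz Sampling rate the template is discretised at.
#' @return An object of class `spike_template`: `waveform` (uV),
#'   `peak_offset` (1-based sample index of the negative peak),
#'   `peak_amplitude_uV`, `width_ms`, `sampling_rate_hz`.
#' @export
spike_template <- function(peak_amplitude_uV = -100, width_ms = 1.5,
                           sampling_rate_hz = 7800) {
  stopifnot(peak_amplitude_uV < 0, width_ms > 0)
  n <- max(5L, as.integer(round(width_ms / 1000 * sampling_rate_hz)))
  u <- seq(0, 1, length.out = n)
  w <- -exp(-((u - 0.35) / 0.10)^2) + 0.30 * exp(-((u - 0.65) / 0.14)^2)
  w <- w - seq(w[1], w[n], length.out = n)  # pin both ends to 0
  w <- w * (abs(peak_amplitude_uV) / abs(min(w)))  # min(w) == peak amplitude
  structure(list(waveform = w, peak_offset = which.min(w),
                 peak_amplitude_uV = peak_amplitude_uV,
                 width_ms = width_ms, sampling_rate_hz = sampling_rate_hz),
            class = "spike_template")
}

#' Simulate raw voltage traces from a spike train set
#'
#' Renders each spike as the template scaled so its negative peak equals the
#' spike's amplitude, centred at the spike time, with overlapping templates
#' summing linearly, plus additive Gaussian noise of SD `noise_sd_uV`.
#' Spikes whose template would extend beyond the trace are truncated with a
#' warning. Fully deterministic given `seed`.
#'
#' @param spikes A [spike_train_set()].
#' @param template A [spike_template()].
#' @param noise_sd_uV Noise standard deviation in uV (>= 0).
#' @param sampling_rate_hz Sampling rate; defaults to the template's.
#' @param electrodes 0-based electrode indices to render; defaults to the
#'   electrodes that carry spikes.
#' @param seed Integer seed for the noise.
#' @return A [raw_recording()].
#' @export
simulate_raw <- function(spikes, template, noise_sd_uV = 5,
                         sampling_rate_hz = template$sampling_rate_hz,
                         electrodes = NULL, seed = 1L) {
  stopifnot(inherits(spikes, "spike_train_set"),
            inherits(template, "spike_template"), noise_sd_uV >= 0)
  n_samples <- as.integer(round(spikes$duration_s * sampling_rate_hz))
  if (is.null(electrodes)) electrodes <- sort(unique(spikes$spikes$electrode))
  w <- template$waveform
  nw <- length(w)
  truncated <- 0L
  traces <- vector("list", length(electrodes))
  names(traces) <- as.character(electrodes)
  for (j in seq_along(electrodes)) {
    e <- electrodes[j]
    set.seed(derive_seed(seed, e + 1L))
    tr <- if (noise_sd_uV > 0) {
      stats::rnorm(n_samples, 0, noise_sd_uV)
    } else {
      numeric(n_samples)
    }
    sel <- spikes$spikes$electrode == e
    t_sp <- spikes$spikes$time_s[sel]
    a_sp <- spikes$spikes$amplitude_uV[sel]
    for (k in seq_along(t_sp)) {
      centre <- as.integer(round(t_sp[k] * sampling_rate_hz)) + 1L
      start <- centre - template$peak_offset + 1L
      idx <- start:(start + nw - 1L)
      keep <- idx >= 1L & idx <= n_samples
      if (!all(keep)) truncated <- truncated + 1L
      scaled <- w * (a_sp[k] / template$peak_amplitude_uV)
      tr[idx[keep]] <- tr[idx[keep]] + scaled[keep]
    }
    traces[[j]] <- tr
  }
  if (truncated > 0L) {
    warning(truncated, " spike template(s) truncated at trace boundaries")
  }
  raw_recording(traces, sampling_rate_hz = sampling_rate_hz,
                geometry = spikes$geometry)
}

#' Expression time-course specification
#'
#' Parameters of a pair of logistic expression curves: NKCC1 decreasing
#' from `nkcc1_start_pct` to `nkcc1_end_pct` and KCC2 increasing from
#' `kcc2_start_pct` to `kcc2_end_pct` over DIV, sharing one logistic shape
#' whose midpoint is placed so that the two noiseless curves intersect
#' exactly at `crossing_div`.
#'
#' @param crossing_div True crossing day; must lie within the range of
#'   `sample_divs`.
#' @param nkcc1_start_pct,nkcc1_end_pct NKCC1 asymptotes (percent); start
#'   must exceed end.
#' @param kcc2_start_pct,kcc2_end_pct KCC2 asymptotes (percent); end must
#'   exceed start, and `nkcc1_start_pct > kcc2_start_pct`,
#'   `kcc2_end_pct > nkcc1_end_pct` so a single crossing exists.
#' @param steepness Logistic rate (1/day, > 0).
#' @param sample_divs Days at which means are reported.
#' @param sem_pct SEM used both to perturb sampled means and reported per
#'   point.
#' @param n_per_point Cultures per point (metadata only).
#' @param seed Integer seed.
#' @return An object of class `expression_curve_spec`.
#' @export
expression_curve_spec <- function(crossing_div, nkcc1_start_pct = 140,
                                  nkcc1_end_pct = 80, kcc2_start_pct = 85,
                                  kcc2_end_pct = 215, steepness = 0.25,
                                  sample_divs = c(8, 16, 26), sem_pct = 3,
                                  n_per_point = 5L, seed = 1L) {
  if (steepness <= 0) stop("steepness must be > 0")
  if (nkcc1_start_pct <= nkcc1_end_pct) {
    stop("NKCC1 must be decreasing (start > end)")
  }
  if (kcc2_end_pct <= kcc2_start_pct) {
    stop("KCC2 must be increasing (end > start)")
  }
  if (nkcc1_start_pct <= kcc2_start_pct || kcc2_end_pct <= nkcc1_end_pct) {
    stop("curves must cross: NKCC1 above KCC2 initially, below finally")
  }
  if (crossing_div < min(sample_divs) || crossing_div > max(sample_divs)) {
    stop("crossing_div must lie within the sampled DIV range")
  }
  structure(list(crossing_div = crossing_div,
                 nkcc1_start_pct = nkcc1_start_pct,
                 nkcc1_end_pct = nkcc1_end_pct,
                 kcc2_start_pct = kcc2_start_pct,
                 kcc2_end_pct = kcc2_end_pct,
                 steepness = steepness, sample_divs = sort(sample_divs),
                 sem_pct = sem_pct, n_per_point = as.integer(n_per_point),
                 seed = as.integer(seed)),
            class = "expression_curve_spec")
}

#' Simulate cotransporter expression series
#'
#' Evaluates the two logistic curves of an [expression_curve_spec()] at the
#' sampled DIVs and perturbs each sampled mean with `Normal(0, sem_pct)`
#' noise (SEM-scaled measurement error). The shared logistic shape
#' `s(t) = 1 / (1 + exp(-steepness (t - m)))` has its midpoint `m` solved
#' in closed form so the noiseless curves intersect exactly at
#' `crossing_div`.
#'
#' @param spec An [expression_curve_spec()].
#' @param genotype Genotype label attached to the returned series.
#' @return A list: `nkcc1` and `kcc2` ([expression_series()]) and
#'   `true_crossing` (the spec's crossing day).
#' @export
simulate_expression <- function(spec, genotype = "synthetic") {
  stopifnot(inherits(spec, "expression_curve_spec"))
  ns <- spec$nkcc1_start_pct; ne <- spec$nkcc1_end_pct
  ks <- spec$kcc2_start_pct;  ke <- spec$kcc2_end_pct
  s_star <- (ns - ks) / ((ke - ks) + (ns - ne))
  m <- spec$crossing_div - log(s_star / (1 - s_star)) / spec$steepness
  sig <- function(t) 1 / (1 + exp(-spec$steepness * (t - m)))
  s_t <- sig(spec$sample_divs)
  nk <- ns + (ne - ns) * s_t
  kc <- ks + (ke - ks) * s_t
  if (spec$sem_pct > 0) {
    set.seed(derive_seed(spec$seed, 1L))
    nk <- nk + stats::rnorm(length(nk), 0, spec$sem_pct)
    kc <- kc + stats::rnorm(length(kc), 0, spec$sem_pct)
  }
  nk <- pmax(nk, 0.1)
  kc <- pmax(kc, 0.1)
  list(
    nkcc1 = expression_series(genotype, "NKCC1", spec$sample_divs, nk,
                              rep(spec$sem_pct, length(nk)),
                              rep(spec$n_per_point, length(nk))),
    kcc2 = expression_series(genotype, "KCC2", spec$sample_divs, kc,
                             rep(spec$sem_pct, length(kc)),
                             rep(spec$n_per_point, length(kc))),
    true_crossing = spec$crossing_div
  )
}
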
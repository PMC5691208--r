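single_train_set <- function(t, duration = max(t) + 1) {
  spike_train_set(data.frame(electrode = 0L, time_s = t, amplitude_uV = -50),
                  array_geometry(1, 1), duration)
}

test_that("the burst rule is applied with strict ISI and length bounds", {
  b <- detect_bursts(single_train_set(c(0, 0.05, 0.10, 0.15, 0.20)))
  expect_equal(nrow(b$bursts), 1L)
  expect_equal(b$bursts$n_spikes, 5L)
  expect_equal(b$bursts$start_s, 0)
  expect_equal(b$bursts$end_s, 0.20)

  # four spikes are not enough
  expect_equal(nrow(detect_bursts(
    single_train_set(c(0, 0.05, 0.10, 0.15)))$bursts), 0L)

  # an exactly-100 ms ISI breaks the run (strict inequality)
  t <- cumsum(c(0, 0.05, 0.05, 0.1, 0.05, 0.05)) + 0.01
  expect_equal(nrow(detect_bursts(single_train_set(t))$bursts), 0L)
})

test_that("burst scanning matches the brute-force oracle on random trains", {
  set.seed(61)
  for (rep in 1:40) {
    t <- random_train(stats::rpois(1, 400) + 5L, duration = 60)
    if (length(t) < 2L) next
    t <- unique(t)
    s <- single_train_set(t, duration = 61)
    got <- detect_bursts(s)$bursts
    want <- oracle_bursts(t)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start_s, want$start_s)
    expect_equal(got$end_s, want$end_s)
    expect_equal(got$n_spikes, want$n_spikes)
  }
})

test_that("MBR averages bursts per minute over active electrodes", {
  # electrode 0: two bursts, 120 tonic-rate spikes; electrode 1: active, no
  # bursts; electrode 2: inactive (too few spikes)
  t0 <- c(seq(0, 0.2, by = 0.05), seq(10, 10.2, by = 0.05),
          seq(20, 600, length.out = 110))
  t1 <- seq(0.5, 599, length.out = 100)
  t2 <- c(1, 300)
  s <- spike_train_set(
    data.frame(electrode = rep(c(0L, 1L, 2L),
                               c(length(t0), length(t1), length(t2))),
               time_s = c(t0, t1, t2), amplitude_uV = -50),
    array_geometry(2, 2), 600)
  b <- detect_bursts(s)
  expect_equal(sort(unique(b$bursts$electrode)), 0L)
  # two electrodes active; (2 + 0) bursts / 2 electrodes / 10 minutes
  expect_equal(b$mbr_per_min, 2 / 2 / 10)
})

test_that("network bursts are found where planted and merged by the window", {
  # one event: 50 of 100 active electrodes spike inside a single 15 ms bin
  set.seed(62)
  g <- array_geometry(10, 10)
  background <- data.frame(
    electrode = rep(0:99, each = 70),
    time_s = stats::runif(7000, 0, 600),
    amplitude_uV = -50)
  ev <- data.frame(electrode = 0:49,
                   time_s = 300.001 + stats::runif(50, 0, 0.013),
                   amplitude_uV = -60)
  sp <- rbind(background, ev)
  sp <- sp[!duplicated(sp[, c("electrode", "time_s")]), ]
  s <- spike_train_set(sp, g, 600)
  nb <- detect_network_bursts(s)
  expect_equal(nrow(nb), 1L)
  expect_gte(nb$peak_participation, 50L)
  expect_lte(nb$start_s, 300.001)
  expect_gte(nb$end_s, 300.014)
})

test_that("event bins merge below the 150 ms horizon and split above it", {
  g <- array_geometry(10, 10)
  # background keeps all 100 electrodes active
  set.seed(63)
  background <- data.frame(electrode = rep(0:99, each = 60),
                           time_s = stats::runif(6000, 0, 600),
                           amplitude_uV = -50)
  # each event is contained in one 15 ms bin (bins are aligned to t = 0)
  burst_at <- function(t0) data.frame(electrode = 0:39,
                                      time_s = t0 + stats::runif(40, 0, 0.009),
                                      amplitude_uV = -60)
  near <- rbind(background, burst_at(100.0055), burst_at(100.0355))
  far <- rbind(background, burst_at(200.0105), burst_at(200.2105))
  dedup <- function(d) d[!duplicated(d[, c("electrode", "time_s")]), ]
  expect_equal(nrow(detect_network_bursts(
    spike_train_set(dedup(near), g, 600))), 1L)
  nb_far <- detect_network_bursts(spike_train_set(dedup(far), g, 600))
  expect_equal(nrow(nb_far[nb_far$start_s > 199 & nb_far$start_s < 201, ]), 2L)
})

test_that("asynchronous Poisson firing produces no network bursts", {
  p <- network_preset(n_active = 100, rate_mu_log10 = log10(0.5),
                      rate_sigma_log10 = 0, seed = 64)
  sim <- simulate_network(p, 600, array_geometry(10, 10))
  expect_equal(nrow(detect_network_bursts(sim$spikes)), 0L)
})

test_that("NB detection is invariant under electrode relabeling and monotone in threshold", {
  sync <- synchronous_set(65, n_electrodes = 60L, duration = 120,
                          n_events = 6L)
  s <- sync$spikes
  nb <- detect_network_bursts(s)
  perm <- sample(0:(n_electrodes(s$geometry) - 1L))
  s2 <- spike_train_set(transform(s$spikes,
                                  electrode = perm[electrode + 1L]),
                        s$geometry, s$duration_s)
  nb2 <- detect_network_bursts(s2)
  expect_equal(nb2$start_s, nb$start_s)
  expect_equal(nb2$peak_participation, nb$peak_participation)

  counts <- vapply(c(0.1, 0.15, 0.3, 0.5, 0.7),
                   function(f) nrow(detect_network_bursts(s, threshold_frac = f)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("genotype presets reproduce the qualitative NB contrast", {
  lg8 <- simulate_network(network_preset_fixture("Lgdel-8div", seed = 66), 300)
  wt8 <- simulate_network(network_preset_fixture("WT-8div", seed = 66), 300)
  expect_equal(nrow(detect_network_bursts(lg8$spikes)), 0L)
  expect_gt(nrow(detect_network_bursts(wt8$spikes)), 0L)
})

test_that("IBI distributions are normalized and located correctly", {
  d <- ibi_distribution(c(0, 1, 2, 3))
  expect_equal(d$ibis_s, c(1, 1, 1))
  trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
  expect_equal(trapz(d$log10_grid, d$density), 1, tolerance = 1e-6)
  expect_lt(abs(d$log10_grid[which.max(d$density)] - 0), 0.01)

  # alternating short/long gaps: bimodal, modes near log10(0.2), log10(5)
  starts <- cumsum(c(0, rep(c(0.2, 5), 30)))
  d2 <- ibi_distribution(starts)
  expect_equal(trapz(d2$log10_grid, d2$density), 1, tolerance = 1e-6)
  # compare against an independent kernel-density oracle on the same values
  l <- log10(diff(starts))
  bw <- 0.05 * diff(range(l))
  oracle <- vapply(d2$log10_grid, function(x0) {
    mean(stats::dnorm((x0 - l) / bw)) / bw
  }, numeric(1))
  oracle <- oracle / trapz(d2$log10_grid, oracle)
  expect_equal(d2$density, oracle, tolerance = 1e-6)
  top2 <- range(d2$log10_grid[order(d2$density, decreasing = TRUE)[1:40]])
  expect_lt(abs(top2[1] - log10(0.2)), 0.1)
  expect_lt(abs(top2[2] - log10(5)), 0.1)

  expect_error(ibi_distribution(c(1)), "at least 2")
})
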
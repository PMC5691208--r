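test_that("tonic spike counts match the Poisson expectation", {
  p <- network_preset(n_active = 100, rate_mu_log10 = -0.5,
                      rate_sigma_log10 = 0, seed = 21)
  sim <- simulate_network(p, 600, array_geometry(16, 16))
  expected <- 100 * 10^-0.5 * 600
  expect_lt(abs(nrow(sim$spikes$spikes) - expected), 4 * sqrt(expected))
  # ground truth records the (clipped) per-electrode rates
  expect_equal(sim$ground_truth$electrodes$rate_hz,
               rep(10^-0.5, 100))
})

test_that("planted network-burst counts match the Poisson expectation", {
  p <- network_preset(n_active = 50, rate_mu_log10 = -1,
                      rate_sigma_log10 = 0.2, nb_rate_per_min = 6,
                      nb_participation = 0.5, nb_spikes_per_electrode = 3,
                      seed = 4)
  sim <- simulate_network(p, 600, array_geometry(16, 16))
  expect_lt(abs(length(sim$ground_truth$nb_times) - 60), 4 * sqrt(60))
})

test_that("the generator is a pure function of preset and seed", {
  p <- network_preset(n_active = 40, rate_mu_log10 = -0.5,
                      rate_sigma_log10 = 0.3, nb_rate_per_min = 3,
                      nb_participation = 0.4, nb_spikes_per_electrode = 3,
                      burst_trains_fraction = 0.2, seed = 9)
  g <- array_geometry(8, 8)
  a <- simulate_network(p, 120, g)
  b <- simulate_network(p, 120, g)
  expect_identical(a$spikes$spikes, b$spikes$spikes)
  expect_identical(a$ground_truth$nb_times, b$ground_truth$nb_times)
  p2 <- p; p2$seed <- 10L
  c <- simulate_network(p2, 120, g)
  expect_false(identical(a$spikes$spikes, c$spikes$spikes))
})

test_that("generated trains respect the 2 ms dead time", {
  p <- network_preset(n_active = 20, rate_mu_log10 = 0.8,
                      rate_sigma_log10 = 0, nb_rate_per_min = 10,
                      nb_participation = 0.8, nb_spikes_per_electrode = 8,
                      nb_jitter_s = 0.003, seed = 2)
  sim <- simulate_network(p, 60, array_geometry(5, 5))
  sp <- sim$spikes$spikes
  for (e in unique(sp$electrode)) {
    isi <- diff(sp$time_s[sp$electrode == e])
    expect_gte(min(isi), 0.002)
  }
})

test_that("zero active electrodes with planted NBs is rejected", {
  expect_error(
    simulate_network(network_preset(0, -0.5, 0, nb_rate_per_min = 1),
                     60, array_geometry(4, 4)),
    "active electrode")
})

test_that("packaged presets encode the genotype contrasts", {
  lgdel8 <- network_preset_fixture("Lgdel-8div")
  wt8 <- network_preset_fixture("WT-8div")
  wt16 <- network_preset_fixture("WT-16div")
  lgdel16 <- network_preset_fixture("Lgdel-16div")
  expect_equal(lgdel8$nb_rate_per_min, 0)
  expect_gt(wt8$nb_rate_per_min, 0)
  expect_gt(lgdel16$rate_mu_log10, wt16$rate_mu_log10)
  expect_error(network_preset_fixture("nope"), "unknown preset")
})

test_that("simulated traces have the requested noise SD and insert spikes", {
  g1 <- array_geometry(1, 1)
  # pure noise: sample SD concentrates on the target
  empty <- spike_train_set(data.frame(electrode = integer(0),
                                      time_s = numeric(0),
                                      amplitude_uV = numeric(0)),
                           g1, duration_s = 10)
  tpl <- spike_template(-100, 1.5, 7800)
  rec <- simulate_raw(empty, tpl, noise_sd_uV = 5, electrodes = 0L, seed = 5)
  expect_lt(abs(stats::sd(rec$traces[["0"]]) - 5) / 5, 0.02)

  # noiseless insertion: minimum equals the spike amplitude at its sample
  one <- spike_train_set(data.frame(electrode = 0L, time_s = 2,
                                    amplitude_uV = -90),
                         g1, duration_s = 5)
  rec0 <- simulate_raw(one, tpl, noise_sd_uV = 0, seed = 5)
  tr <- rec0$traces[["0"]]
  expect_equal(min(tr), -90)
  expect_equal(which.min(tr), round(2 * 7800) + 1L)

  # same seed, same trace; spike near the trace end is truncated + warned
  rec0b <- simulate_raw(one, tpl, noise_sd_uV = 0, seed = 5)
  expect_identical(rec0$traces, rec0b$traces)
  late <- spike_train_set(data.frame(electrode = 0L, time_s = 4.9999,
                                     amplitude_uV = -90),
                          g1, duration_s = 5)
  expect_warning(simulate_raw(late, tpl, noise_sd_uV = 0, seed = 1),
                 "truncated")
})

test_that("spike templates are biphasic with an exact negative peak", {
  tpl <- spike_template(-120, 2, 7800)
  w <- tpl$waveform
  expect_equal(min(w), -120)
  expect_equal(w[1], 0)
  expect_equal(w[length(w)], 0)
  expect_gt(max(w), 0)  # positive after-potential
  expect_equal(which.min(w), tpl$peak_offset)
})

test_that("expression curves cross exactly at the requested DIV", {
  for (cd in c(10, 18, 20.5, 24)) {
    spec <- expression_curve_spec(crossing_div = cd, sem_pct = 0,
                                  sample_divs = seq(8, 26, by = 0.5))
    sim <- simulate_expression(spec)
    est <- estimate_switch(sim$nkcc1, sim$kcc2)
    # dense noiseless sampling localizes the logistic crossing tightly
    expect_lt(abs(est$crossing_div - cd), 0.05)
  }
  # crossing at the first sampled DIV: KCC2 >= NKCC1 everywhere
  sim8 <- simulate_expression(expression_curve_spec(8, sem_pct = 0))
  expect_true(all(sim8$kcc2$points$mean_pct >= sim8$nkcc1$points$mean_pct))
  expect_equal(estimate_switch(sim8$nkcc1, sim8$kcc2)$crossing_div, 8)
  expect_error(expression_curve_spec(18, steepness = 0), "steepness")
  expect_error(expression_curve_spec(30), "within the sampled DIV range")
})

test_that("expression simulation is seed-deterministic with SEM noise", {
  spec <- expression_curve_spec(18, sem_pct = 3, seed = 12)
  a <- simulate_expression(spec)
  b <- simulate_expression(spec)
  expect_identical(a$nkcc1$points, b$nkcc1$points)
  expect_identical(a$kcc2$points, b$kcc2$points)
})
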
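# Genotype-like network presets for the synthetic developing-network
# generator. Rates in log10 Hz, NB rates in events/min, jitter in seconds.
# Lgdel-8div deliberately has nb_rate_per_min = 0 (immature deletion-model
# networks show no network bursts at 8 DIV); Lgdel-16div has a higher mean
# rate than WT-16div (hyper-excitable at 16 DIV).
WT-8div:
  n_active: 300
  rate_mu_log10: -0.7
  rate_sigma_log10: 0.30
  nb_rate_per_min: 2
  nb_participation: 0.30
  nb_spikes_per_electrode: 3
  nb_jitter_s: 0.010
  burst_trains_fraction: 0.10
WT-16div:
  n_active: 800
  rate_mu_log10: -0.30
  rate_sigma_log10: 0.35
  nb_rate_per_min: 8
  nb_participation: 0.50
  nb_spikes_per_electrode: 5
  nb_jitter_s: 0.010
  burst_trains_fraction: 0.30
Lgdel-8div:
  n_active: 200
  rate_mu_log10: -0.9
  rate_sigma_log10: 0.30
  nb_rate_per_min: 0
  nb_participation: 0
  nb_spikes_per_electrode: 0
  nb_jitter_s: 0.010
  burst_trains_fraction: 0.05
Lgdel-16div:
  n_active: 900
  rate_mu_log10: -0.05
  rate_sigma_log10: 0.35
  nb_rate_per_min: 4
  nb_participation: 0.35
  nb_spikes_per_electrode: 5
  nb_jitter_s: 0.015
  burst_trains_fraction: 0.25
Dgcr8-16div:
  n_active: 700
  rate_mu_log10: -0.35
  rate_sigma_log10: 0.35
  nb_rate_per_min: 6
  nb_participation: 0.45
  nb_spikes_per_electrode: 4
  nb_jitter_s: 0.012
  burst_trains_fraction: 0.25
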
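---
title: "Methods: spike-train, burst and development analysis for high-density MEAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-train, burst and development analysis for high-density MEAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdmea)
```

## Scope and data model

`hdmea` analyses spontaneous activity of developing neuronal networks
recorded on high-density CMOS multielectrode arrays — by default a 64 x 64
grid of 4096 electrodes (21 um electrodes, 42 um pitch) sampled at 7.8 kHz
per electrode — and estimates the developmental GABA-polarity switch from
chloride-cotransporter expression time courses. The central container is
the `spike_train_set`: per-electrode spike times in seconds and
negative-peak amplitudes in microvolts (stored with their sign), plus the
recording duration and culture metadata. Electrodes are indexed 0-based
and row-major; percent-of-baseline quantities are kept on the printed
scale (baseline = 100), never as fractions.

## Spike detection

Extracellular spikes are detected with a differential-threshold detector
in the precise-timing tradition: per electrode, the noise SD is estimated
and the threshold set to 9 times it; a spike is emitted at each local
negative minimum whose peak-to-peak excursion to the largest trace value
within +/- 2 ms (the peak lifetime) exceeds the threshold. The timestamp
is the negative-peak sample and the amplitude the trace value there;
detections within a 1 ms refractory period keep the larger-magnitude peak.

Two choices deserve comment. First, the noise SD defaults to the scaled
median absolute deviation, `median(|x - median(x)|) / 0.6745`, because a
plain sample SD is inflated by the spikes themselves; the plain SD remains
available (`noise_estimator = "sd"`). Second, the peak-to-peak criterion
uses the running maximum of the trace in the window rather than an
enumeration of local maxima; the two coincide except when the window's
largest value sits on a monotone run at the window edge, and the running
maximum is cheaper and deterministic. The detector is
translation-equivariant and invariant to rescaling the trace (threshold
and excursion scale together) — both properties are tested.

The multiplier of 9 is the only quotable detection constant in the source
analysis; the 2 ms peak lifetime and 1 ms refractory period are the
conventional settings of this detector family and are exposed as
parameters.

## Activity metrics

Per-electrode rate is spike count over duration. *Active* electrodes are
those with rates between 0.1 and 10 events/s — both bounds inclusive, the
conservative reading of "between", and tested explicitly at the
boundaries. The network mean firing rate (MFR) averages rates over active
electrodes only (with no active electrode it is reported as 0); the
64 x 64 rate map applies no filtering. Amplitude summaries average
negative peaks at least as large in magnitude as a conservative cutoff
(default -250 uV, i.e. amplitude <= -250).

## Burst and network-burst analysis

A single-electrode burst is a maximal run of at least 5 consecutive
spikes with every inter-spike interval strictly below 100 ms. The mean
bursting rate (MBR) averages bursts per minute over active electrodes.
The implementation is run-length based and is property-tested against an
exhaustive spike-by-spike scan on hundreds of random trains.

Network bursts (NBs) are synchrony events: time is partitioned into 15 ms
bins aligned to t = 0; per-bin participation is the number of distinct
active electrodes firing in the bin; bins whose participation strictly
exceeds 15% of the active-electrode count are event bins; event bins
separated by less than 150 ms merge into one NB. The 15% threshold base
is the active-electrode count (a participation threshold), the standard
MEA criterion and scale-free in firing rate — the source phrasing ("15% of
the total network spiking activity") admits several readings and this one
is adopted and documented. NB count is monotone non-increasing in the
threshold, and the detector is invariant to electrode relabeling.

Inter-burst intervals are successive onset-to-onset differences. Their
distribution is summarised as a Gaussian kernel density of `log10(IBI)`
with bandwidth equal to 5% of the log10-IBI range, evaluated exactly (no
FFT binning) on a 256-point grid spanning the data +/- 3 bandwidths and
renormalized to integrate to 1 within 1e-6. The 5% rule preserves the
proportional-bandwidth idea of the source description, which is not
implementable verbatim; onset-to-onset intervals were chosen over
end-to-onset.

## Firing-rate distributions

Active-electrode rates are summarised in log space: a 20-bin histogram of
`log10(rate)` over the active band `[-1, 1]`, with occurrences normalized
by the full array size (4096), so the histogram totals
`n_active / 4096`. The lognormal fit is the mean and SD of the raw log10
rates — bin-free and deterministic, rather than a least-squares fit to the
histogram; the two agree in the mean to within bin resolution. Fits are
flagged unavailable below 10 active electrodes. Shifts between conditions
are differences of fitted means: negative is a shift toward lower
frequencies. Scaling all rates by `c` moves the mean by exactly
`log10(c)` and leaves the SD unchanged.

## Homeostasis

Perturbation experiments are read out on the percent-of-baseline scale.
`classify_homeostasis` calls the early response (default the 2 h point)
an increase or decrease only outside a +/- 5% dead band, and calls the
network restored when the late point (default 48 h) is within a tolerance
of baseline. The default tolerance is 12%: the published trajectories
place clearly-restored endpoints at 101.4% and 89.1% and a
clearly-unrestored one at 64.1%, and 12% is the narrowest round band that
separates them; it is a configurable parameter, not a claim. Verdicts are
invariant under uniform rescaling of the raw rates, since normalization
removes the scale.

The packaged timeline fixture carries one value (83.76 +/- 8.05%) that the
source tables print for two distinct conditions (18 DIV bumetanide-treated
and 26 DIV untreated deletion-model cultures) — almost certainly a
typographical duplication; both rows are kept as printed.

## GABA-polarity switch estimation

NKCC1 (chloride importer) expression falls with development while KCC2
(chloride extruder) rises; their crossing marks the switch of GABA-A
signalling from depolarizing to hyperpolarizing. With only three sampled
DIVs per genotype, the estimator interpolates the two mean trajectories
piecewise-linearly and reports the smallest DIV at which
`KCC2 - NKCC1 >= 0`. Equality at a sampled DIV counts as a crossing, so a
genotype whose trajectories are normalized to a common 100% at the first
sampled DIV crosses there; if KCC2 stays below NKCC1 throughout, no
crossing is reported. On the packaged published values this yields 8 DIV
for WT and crossings between 16 and 26 DIV for both mutant genotypes
(19.66 and 16.53 DIV). These differ somewhat from the graphical estimates
reported alongside the source figures (~20.5 and ~17.5 DIV), which
plausibly interpolated per-sample curves rather than the printed means;
with only the printed means available, piecewise-linear interpolation is
the only procedure that adds no assumptions.

Uncertainty comes from a parametric bootstrap: each sampled mean is
redrawn as `Normal(mean, SEM)` — raw per-culture values are not published,
so resampling data is not an option — and the crossing is recomputed per
replicate; the CI is the 2.5–97.5 percentile range of defined crossings,
with the fraction of no-crossing replicates reported. The bootstrap is
seeded and fully reproducible.

## Synthetic data: what it emulates and what it does not

No raw recordings are deposited with the source analysis, so every
downstream stage is validated on synthetic data with known ground truth:

- **Spike trains** (`simulate_network`): per-electrode tonic firing is
  homogeneous Poisson with rates drawn from a lognormal
  (`log10 r ~ Normal(mu, sigma)`, clipped to `[0.01, 20]` Hz to stay near
  the analysable range); NB events are a Poisson process in time, each
  recruiting a binomial subset of electrodes that add
  `Poisson(nb_spikes)` spikes with Gaussian jitter; a preset fraction of
  electrodes also emits intrinsic bursts (2 per minute, 5+ spikes at
  20–80 ms ISIs). A 2 ms dead time removes unphysical ISIs. Amplitudes
  are electrode-specific negative means (40–120 uV) with 15% spike-to-spike
  variation. One global seed expands deterministically into per-electrode
  substreams.
- **Raw traces** (`simulate_raw`): each spike inserts a biphasic template
  (dominant negative lobe, smaller positive after-potential, pinned to 0
  at both ends) scaled to the spike's amplitude, plus white Gaussian
  noise. Real extracellular noise is neither white nor stationary, and
  real waveforms vary by cell and position; passing detection tests here
  demonstrates correctness of the detector's logic, not field-ready
  performance on real recordings.
- **Expression curves** (`simulate_expression`): NKCC1 falls and KCC2
  rises along a shared logistic shape whose midpoint is solved in closed
  form so the noiseless curves intersect exactly at the requested DIV;
  sampled means get `Normal(0, SEM)` perturbations.

The packaged genotype presets (`WT-8div`, `WT-16div`, `Lgdel-8div`,
`Lgdel-16div`, `Dgcr8-16div`) encode the qualitative developmental
contrasts — no NBs in the immature deletion model at 8 DIV, a
hyper-excitable deletion model at 16 DIV — with parameter values chosen
once as plausible for dissociated hippocampal cultures on these arrays
(hundreds of active electrodes, tonic rates centred near 0.2–0.9 Hz, NB
rates of 2–8 per minute recruiting 30–50% of electrodes). The source
analysis publishes no generative model, so these are calibration choices
of this package, not claims about the data.

## Numerical and design choices

- Correlated NB recruitment, refractoriness beyond the 2 ms dead time,
  spatial propagation and conductance-based dynamics are deliberately out
  of scope of the generator.
- The bootstrap-coverage simulation samples expression every 2 DIV. On
  the sparse 3-point experimental grid the piecewise-linear estimator
  carries a deterministic interpolation bias relative to the underlying
  logistic crossing (about a third of a day for typical parameters) that
  no bootstrap can absorb; the 2-day grid isolates the property actually
  claimed — that the seeded bootstrap CI covers the truth for an unbiased
  estimator. The 3-point estimates themselves are exact for piecewise-linear
  trajectories, which is all the printed means can support.
- Bins for NB detection are aligned to t = 0 and non-overlapping;
  alignment is unstated in the source and fixed for determinism.
- Problem sizes in the test-suite simulations (10-minute recordings,
  60–900 electrodes, 20–200 Monte-Carlo repetitions, 400–2000 bootstrap
  replicates) were chosen so closed-form expectations have comfortable
  margins at 3–4 SDs while a full run stays interactive on a laptop.
- Degenerate inputs: an all-silent array yields MFR 0 with an empty
  active mask; amplitude summaries with no qualifying spike flag an `NA`
  mean; identical IBIs fall back to a small fixed kernel bandwidth
  (1e-3 log10 units) to keep the density proper.

## Worked example

```{r example, eval = FALSE}
library(hdmea)

# Published expression values -> switch estimates with bootstrap CIs
series <- read_expression_csv(expression_fixture_path())
bootstrap_switch(series$Lgdel.NKCC1, series$Lgdel.KCC2,
                 n_boot = 2000, seed = 1)

# Simulate a 16-DIV-like WT network and analyse it end to end
cfg <- pipeline_config(preset = "WT-16div", duration_s = 600, seed = 1)
summary <- run_pipeline(cfg)
str(summary)
```

## Limitations

The pipeline consumes already-quantified expression and timeline tables;
image quantification, qRT-PCR analysis and group-level hypothesis testing
(ANOVA and friends, available in base R) are outside its scope, as are
spike sorting, proprietary acquisition formats and "superburst"
classification, for which no published criterion exists.
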
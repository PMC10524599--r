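# afferent

Spike-train timing and SNARE-disassembly kinetics analyses for
hair-cell synaptic physiology.

Zebrafish lateral-line hair cells signal to afferent neurons through
ribbon synapses, and defects in the synaptic-vesicle machinery (such as
point mutations in the SNARE-disassembly ATPase NSF) show up not as
fewer spikes but as *mistimed* ones: looser phase locking to a
sinusoidal stimulus, irregular and bursty spontaneous firing, and slow
recovery of spontaneous activity after prolonged stimulation. In
parallel, the biochemical lesion shows up in vitro as a slower initial
rate of fluorescence dequenching when NSF/alpha-SNAP disassemble
labelled SNARE complexes. `afferent` implements the complete analysis
chain for both data types, plus seeded synthetic generators for every
input class so that each stage is verifiable end to end without access
to raw recordings.

## What it computes

**Evoked timing (phase locking).** Spike latencies are normalized to
the stimulus cycle (`assign_phases()`): each spike gets a fraction
φ ∈ [0, 1) of the period T = 1/f. Vector strength is the mean resultant
length of the unit vectors at angles θᵢ = 2πφᵢ,

    r = (1/n) * sqrt((Σ cos θᵢ)² + (Σ sin θᵢ)²),

with r = 1 for perfect locking and 0 for uniform phases
(`vector_strength()`). Latency histograms (50 bins/period) are fitted
with a Gaussian a·exp(−(x−µ)²/2σ²) to give the preferred latency µ ± SE
and spread σ in period fractions, and the peak latency in ms
(`latency_histogram()`, `fit_gaussian_latency()`).

**Spontaneous timing.** Interspike-interval mean and CV
(`compute_isi()`, `isi_stats()`); recurrence maps of consecutive
intervals with quadrant fractions and a shuffle-nulled burst-spread
index (`isi_recurrence()`, `burst_metrics()`); one- versus two-phase
exponential fits to the ISI histogram compared by the extra
sum-of-squares F test (`fit_isi_exponential()`, `extra_ss_f_test()`);
and post-stimulus recovery summarized by the cumulative spike count,
time to the k-th spike, and late-phase rate (`recovery_curve()`,
`recovery_metrics()`).

**Spike detection.** Robust threshold detection for loose-patch
action-current traces: MAD-based noise SD, excursion extrema as spike
times, refractory enforcement (`detect_spikes()`).

**Dequenching kinetics.** Initial disassembly rates as OLS slopes over
the first 112.5 s (ternary SNARE substrate) or 222.5 s (binary) after
trituration, with SEs from the regression, and one-way ANOVA / t-test
comparisons across conditions (`read_plate()`, `initial_rate()`,
`initial_rates()`, `compare_rates()`).

**Generators.** `sim_phase_locked_train()` (wrapped-normal cycle
latencies; population r = exp(−2π²σ²) exactly),
`sim_spontaneous_train()` (gamma renewal or two-state bursty),
`sim_recovery_train()` (inhomogeneous Poisson with delayed-exponential
rate), `sim_action_current_trace()` (biphasic waveforms in 1-kHz
low-passed Gaussian noise), `sim_plate()` (saturating dequenching
curves). All take explicit seeds and are bit-reproducible.

Results come back as tibbles; fitted objects have `tidy()`/`glance()`
methods and `autoplot()` figures; `run_pipeline()` drives all stages
from one configuration and writes JSON reports with provenance.

## Worked example

A 60-s, 60-Hz recording from a tightly locked ("WT-like") afferent:

```r
library(afferent)
stim <- stimulus_spec(60, duration_s = 60, reporting_period_ms = 16.6)
wt <- sim_phase_locked_train(stim, mean_fraction = 0.258,
                             sd_fraction = 0.0691, p_spike = 0.32,
                             seed = 1, label = "WT-like")
ph <- assign_phases(wt, stim)
vector_strength(ph)
#> # A tibble: 1 × 3
#>       r mean_phase_fraction     n
#>   <dbl>               <dbl> <int>
#> 1 0.903               0.259  1161
glance(fit_gaussian_latency(latency_histogram(ph, 50)))
#> # A tibble: 1 × 7
#>   mu_fraction   mu_se sigma_fraction peak_latency_ms reporting_period_ms ...
#> 1       0.261 0.00122         0.0722            4.33                16.6
spike_rate(wt, 0, 60)
#> [1] 19.35
```

The 1161 spikes lock at vector strength r ≈ 0.90 with a preferred
latency of 0.26 of the stimulus period — 4.3 ms into the 16.6-ms cycle
— at 19 spikes/s. A "mutant-like" cell generated with a broader,
delayed latency distribution (`mean_fraction = 0.298`,
`sd_fraction = 0.1033`, seed 2) gives r ≈ 0.82, peak latency 5.1 ms at
16 spikes/s: same firing rate to within noise, visibly degraded timing.

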
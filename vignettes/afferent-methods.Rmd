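---
title: "Models and methods behind the afferent analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the afferent analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afferent)
library(dplyr)
```

This vignette explains what each analysis in `afferent` computes, the
assumptions it makes, and why the numerical and design choices were made
the way they were. The package analyses two kinds of data from
hair-cell synaptic physiology: loose-patch recordings of lateral-line
afferent neuron firing (evoked by a sinusoidal fluid-jet stimulus, or
spontaneous), and plate-reader fluorescence-dequenching assays of
NSF/alpha-SNAP-driven SNARE-complex disassembly. Because such
recordings are rarely distributable, every analysis is paired with a
seeded generator that produces data with the statistical structure the
analysis assumes; the test suite uses these generators as ground truth.

## Phase locking: the latency model and vector strength

A sinusoidal stimulus of frequency $f$ partitions time into cycles of
period $T = 1/f$. Each spike inside the stimulus window is assigned its
latency within the cycle that contains it, expressed as a fraction
$\phi \in [0, 1)$ of the period (`assign_phases()`). Two summaries are
computed from the phase set:

* **Vector strength.** Each phase becomes a unit vector at angle
  $\theta_i = 2\pi\phi_i$ and
  $r = \frac{1}{n}\sqrt{(\sum_i \cos\theta_i)^2 +
  (\sum_i \sin\theta_i)^2}$. $r = 1$ means perfect locking; $r = 0$
  a uniform phase distribution.
* **Latency histogram with a Gaussian fit.** Phases are binned (50
  bins per period by default, matching common practice of fitting the
  histogram rather than the raw latencies) and
  $a\,e^{-(x-\mu)^2/2\sigma^2}$ is fitted to bin centers versus counts
  by Levenberg–Marquardt least squares. The fit reports $\mu$ and
  $\sigma$ in period fractions, the standard error of $\mu$ from the
  fit covariance, and the peak latency in milliseconds,
  $\mu \times$ `reporting_period_ms`.

The evoked generator (`sim_phase_locked_train()`) draws at most one
spike per cycle, with per-cycle firing probability `p_spike`, and the
latency from a **wrapped normal** distribution with mean fraction $\mu$
and circular SD $\sigma$ (period fractions). The wrapped normal was
chosen over the von Mises because at the concentrations relevant here
($\sigma \lesssim 0.15$ periods) the two are practically
indistinguishable, while the wrapped normal gives an exact closed form
for the population vector strength,

$$ r = e^{-2\pi^2\sigma^2}, $$

which the test suite uses as an independent oracle: sample $r$ over
seeds must agree with the closed form within three standard errors
across a grid of $\sigma$ values. The same closed form maps the
vector strengths 0.96, 0.91 and 0.81 — the wild-type 20-Hz, wild-type
60-Hz and mutant 60-Hz phase-locking conditions — to circular SDs of
0.0455, 0.0691 and 0.1033 periods, which is why those three values are
the generator defaults exercised throughout the tests.

```{r vs-demo}
stim <- stimulus_spec(60, duration_s = 50, reporting_period_ms = 16.6)
train <- sim_phase_locked_train(stim, mean_fraction = 0.298,
                                sd_fraction = 0.1033, seed = 1)
phases <- assign_phases(train, stim)
vector_strength(phases)
glance(fit_gaussian_latency(latency_histogram(phases, 50)))
```

Three numerical details matter:

* **Reporting period.** The exact 60-Hz period is 16.667 ms, but
  figure legends in this literature typically round it to 16.6 ms
  before converting latency fractions to milliseconds
  ($0.258 \times 16.6 = 4.28$ ms, $0.298 \times 16.6 = 4.95$ ms,
  whereas the exact period would give 4.30 ms). `stimulus_spec()`
  therefore accepts a `reporting_period_ms` distinct from the exact
  period; it affects only the millisecond conversion, never the phase
  assignment.
* **Wrap handling.** A linear Gaussian fit is ill-posed when the
  preferred phase sits near the 0/1 boundary. If the circular mean of
  the histogram lies within two circular SDs of the boundary, phases
  are rotated by half a period, fitted, and the mean rotated back.
* **Phase snapping.** The phase fraction is rounded at $10^{-12}$
  resolution so that spike times which are exact period multiples map
  to fraction 0 rather than $0.999\ldots$ through floating-point
  modulus error.

## Spike detection in action-current traces

Loose-patch action currents are rendered and detected as follows. The
generator (`sim_action_current_trace()`) places a stereotyped biphasic
(negative-then-positive) waveform at each spike time on top of Gaussian
white noise, then applies a single-pole 1-kHz low-pass mirroring a
typical acquisition filter at the default 50-microsecond sampling.
Both amplitude parameters are defined on the *recorded* trace: the
spike kernel is pre-scaled so its post-filter negative peak equals
`spike_amplitude_au`, and the white-noise input is pre-scaled by the
inverse of the filter's noise gain so the recorded baseline SD equals
`noise_sd_au`. The signal-to-noise ratio of a simulated recording is
therefore exactly `spike_amplitude_au / noise_sd_au`, which makes the
detection round-trip properties (recall and precision at a given SNR)
well-defined.

`detect_spikes()` estimates the baseline level as the median and the
noise SD as the median absolute deviation (scaled by 1.4826), so
spikes themselves do not inflate the threshold; it then groups
supra-threshold samples (default 5 SD, negative polarity) into
contiguous excursions, takes the extremum of each excursion as the
spike time — robust to the exact threshold, unlike the first crossing
— and enforces a refractory separation (default 1 ms). Detection is
invariant to constant offsets by construction. At SNR 8 and the
default threshold the suite requires recall and precision of at least
0.99 against generator ground truth across 20 seeds.

## Spontaneous timing: ISI statistics, recurrence maps, model selection

Interspike intervals are first differences of spike times
(`compute_isi()`); recordings acquired as consecutive fixed-length
sweeps are handled by excluding intervals that span a sweep boundary
(`split_sweeps()`), since those gaps are acquisition artifacts.
`isi_stats()` reports the mean ISI and the coefficient of variation
(sample SD over mean): about 1 for Poisson-like firing, near 0 for
clock-like firing, above 1 for bursting.

The **recurrence map** (`isi_recurrence()`) plots each interval against
its predecessor. `burst_metrics()` partitions the pairs into quadrants
at a threshold — the median ISI by default, a scale-free choice since
no canonical threshold exists — with ties counted as "short", and
reports the four quadrant fractions plus a **burst-spread index**: the
observed short-short fraction minus its expectation under random
reordering of the intervals (mean over 100 shuffles). The shuffle null
makes the index a calibrated statistic: it is centred at 0 for any
renewal train, exactly 0 for a clock-like train (every pair ties into
short-short regardless of order), and positive when short intervals
cluster in time. Within-burst clustering of short intervals was chosen
as the index's signature deliberately: for a two-state (burst/quiet)
Markov-modulated train, *both* short and long intervals form runs, so
statistics built on the off-diagonal ("transition") quadrants or on
the complement of the long-long quadrant are actually *depressed*
relative to shuffle and would assign bursting a negative score. The
short-short excess is the one quadrant statistic whose sign reliably
separates bursty from renewal firing under this model.

The **ISI histogram model selection** follows standard curve-fitting
practice: the histogram (50 bins to the 99th-percentile interval,
zero-count bins excluded) is fitted with one-phase
($A e^{-t/\tau}$) and two-phase
($A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2}$) exponentials, and the models
are compared with the extra sum-of-squares F test:
$F = \frac{(SS_1 - SS_2)/(df_1 - df_2)}{SS_2/df_2}$, with
$df = (\text{fitted bins}) - (\text{parameters})$ and the two-phase
model preferred at $p < 0.05$. The fits use variable projection —
time constants optimised on the log scale with amplitudes solved
linearly at each step (Nelder–Mead from three starting geometries for
the two-phase case) — which is deterministic and immune to the
convergence failures raw nonlinear least squares exhibits on noisy
histograms. The suite calibrates the test's type-I error under
one-phase truth with Gaussian bin noise (the regime where the F
reference distribution is exact) and requires a rejection rate in
[0.03, 0.08] at $\alpha = 0.05$ over 1000 replicates.

**Recovery after prolonged stimulation** is summarised by the
cumulative spike count after stimulus offset (`recovery_curve()`), the
time to the $k$-th recovered spike, and the late-phase slope of the
cumulative curve (`recovery_metrics()`). The matching generator is an
inhomogeneous Poisson process (by thinning) with rate
$\lambda(t) = \lambda_0 (1 - e^{-\max(t - d, 0)/\tau})$ — silent for a
dead time $d$, then an exponential approach to the baseline rate —
whose exact integral `recovery_expected_count()` serves as the oracle
for the cumulative curve.

## Dequenching kinetics: initial rates and comparisons

In the disassembly assay, dye-labelled SNARE complexes self-quench;
NSF/alpha-SNAP-driven disassembly separates the fluorophores, so
fluorescence rises as complexes come apart. The initial disassembly
rate is the ordinary least-squares slope of fluorescence versus time
over a fixed window from trituration (the first sample): 112.5 s for
ternary-complex substrates and 222.5 s for the slower binary
complexes, the windows used in this assay family (45 and 89 points at
the 2.5-s read interval). No baseline normalisation is applied —
normalising would rescale the rates — so slopes are in raw AU/s, with
standard errors from the regression. Replicate rates are compared
across conditions by one-way ANOVA (or a two-tailed t test for two
groups) via `compare_rates()`.

The plate generator (`sim_plate()`) is phenomenological:
$F(t) = f_0 + (f_{max} - f_0)(1 - e^{-k_{obs} t}) + \text{drift}\cdot t
+ \varepsilon$, with Gaussian read noise. It does not model NSF ATPase
cycles or SNARE zippering mechanistically; the reaction stoichiometry
(NSF:SNARE:alpha-SNAP combined 1:5:25; 1720 nM labelled SNARE, 1.96 uM
alpha-SNAP, 60 uL) is carried as metadata only. The default
`plate_design()` encodes the qualitative outcome of the I209N
disassembly experiments — ternary: mutant far slower than WT at both
NSF concentrations and essentially inactive at 8.3 nM; binary: mutant
slightly slower at 42.2 nM, strongly impaired at 8.3 nM; no-NSF
controls flat — with $k_{obs}$ values (0.020/0.002 and 0.008/0.0002
per s for ternary WT/mutant at 42.2/8.3 nM; 0.004/0.003 and
0.0015/0.0002 for binary) chosen once to respect that ordering at
plate-reader-realistic signal levels ($f_0 = 100$, $f_{max} = 200$ AU,
1 AU noise, drift 0.002 AU/s, $n = 3$ replicates). No absolute rates
are claimed: the published record for this assay prints trace families
and significance calls, not numeric rates, so only the ordering and
significance structure are meaningful targets.

```{r kinetics-demo}
rates <- initial_rates(sim_plate(plate_design(), seed = 1))
rates |>
  filter(variant != "none") |>
  group_by(variant, nsf_nM, complex_kind) |>
  summarise(rate_au_per_s = mean(slope_au_per_s), .groups = "drop") |>
  arrange(complex_kind, desc(nsf_nM), variant)
```

## The pipeline and reports

`run_pipeline()` ties the stages together from a single configuration
(list or YAML): simulate or load inputs, analyse, and write one JSON
report per stage plus a `rates.csv`. Reports have a flat
`metrics` section, a `units` section, and a `provenance` block
(package version, master seed, configuration hash) so that identical
configuration and seed reproduce identical numeric payloads; a failing
stage aborts, names itself, and removes partial outputs. Every
generator takes an explicit seed (library default 0), and per-stage
streams are derived from the master seed.

## What the generators do and do not establish

The generators emulate the statistical structure the analyses assume:
wrapped-normal cycle latencies, gamma/Markov-modulated renewal ISIs,
delayed-exponential Poisson recovery, biphasic waveforms in filtered
Gaussian noise, saturating dequenching curves with Gaussian read
noise. Real recordings differ in known ways: noise is not exactly
Gaussian or stationary, evoked firing shows cycle-skipping statistics
and adaptation not captured by an independent per-cycle Bernoulli
draw, multi-spike cycles can occur at low frequencies, bursting need
not be two-state Markov, and plate readers drift nonlinearly. Passing
tests therefore demonstrate that the *analyses* are correct and
well-calibrated on data satisfying their stated assumptions — not that
those assumptions hold for any particular recording. Parameters whose
values the study conditions fix (circular SDs, mean fractions, NSF
concentrations, rate windows) are defaults; everything else (noise
levels, rate constants, burst transition probabilities) is a stated
modelling choice documented above and held fixed across the suite.

Problem sizes used by the suite and the reproduction script — 50,000
phases for vector-strength checks, 3,000 spikes for latency-fit
recovery, 400-s spontaneous trains, 1000 replicates for test
calibration, 10–20 seeds for generator contrasts — were chosen so
every stochastic check has comfortable statistical margin while the
whole suite stays desk-scale.

## Known limitations

* Spike detection assumes single-unit recordings; no sorting is
  attempted.
* The Gaussian latency fit assumes a unimodal phase preference; it
  will not flag bimodal locking.
* Two-phase exponential fits with nearly equal time constants are
  flagged as degenerate rather than regularised.
* The recovery late-rate slope is computed on spike-time points of
  the cumulative curve; for nearly silent late windows it reports 0
  with a warning rather than extrapolating.
* Circular significance tests (e.g. Rayleigh) are deliberately out of
  scope, as are mechanistic kinetic models.
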
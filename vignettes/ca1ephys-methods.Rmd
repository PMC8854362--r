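---
title: "Methods: CA1 electrophysiology feature extraction and its synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CA1 electrophysiology feature extraction and its synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ca1ephys)
```

## What the package computes

`ca1ephys` reimplements, as tested and reusable code, the analysis chain of
a slice-electrophysiology characterization of hippocampal CA1: intrinsic
membrane properties from current-clamp step families, spontaneous EPSC
(sEPSC) statistics from voltage-clamp traces, evoked field-potential and
theta-burst LTP measurements, and the group statistics (one-way ANOVA,
Levene's homogeneity test, Tukey's post hoc test, mean ± SEM tables with
stars) used to compare treatment groups — here motivated by the
valproic-acid (VPA) rat model of autism, where such comparisons are made
between control and prenatally exposed animals of both sexes at two ages.

Animal recordings cannot be regenerated, so validation is property-based:
the package ships a synthetic-data generator whose outputs carry exact
ground truth, and every extractor is tested against it. The generator has
two modes:

* **Parametric mode** (`construct_parametric_step_responses()`): noiseless
  waveforms assembled so that each extractor, under the package's stated
  measurement conventions, returns the target values *exactly*. This is the
  oracle for the round-trip contract `extract(construct(target)) = target`.
* **Mechanistic mode** (`simulate_current_step_cell()`): an
  exponential-integrate-and-fire (EIF) neuron with a slow
  hyperpolarization-activated (h) conductance. It produces genuinely
  dynamical sweeps — an emergent rheobase, threshold kink, and voltage sag —
  against which the extractors are checked in analytically known limits.

## Intrinsic-property conventions

Given a family of 350-ms current steps (default −160 → +300 pA in 5 pA
increments, 20 kHz):

* **Resting potential** — mean of all pre-step samples pooled across sweeps.
* **Membrane resistance** — OLS slope of the steady-state deflection (mean
  of the final 50 ms of the step minus the pre-step baseline) against
  injected current, negative levels only, in MΩ. Negative steps avoid the
  subthreshold spike-initiation nonlinearity; a 50-ms window rather than a
  point resists noise.
* **Voltage sag** — per negative step, the minimum of the step response
  minus its end value (mean of the final 10 ms); ≤ 0 and independent of any
  baseline offset. The **sag index** is the OLS slope (intercept fitted,
  slope reported) of sag against hyperpolarizing current magnitude in nA.
  Fitting an intercept matches the conventional fitted line through the
  sag–current plot; the algebraically equivalent positive-sag convention
  gives the same slope.
* **Spike detection** — a spike is a local maximum above 0 mV, preceded
  within 5 ms by an upward crossing of −20 mV; maxima closer than 2 ms are
  merged (higher kept). The per-spike threshold is the start of the final
  rapid upstroke: the earliest sample before the peak from which the
  two-point dV/dt stays above 20 mV/ms. No published criterion accompanies
  the source analysis; these four constants are conventional for somatic
  CA1 recordings, unambiguous on both generator modes, and all configurable
  (`spike_config()`).
* **Rheobase** — smallest positive level with ≥ 1 detected spike, hence
  grid-quantized: the 5-pA protocol increment makes finer resolution
  meaningless, and continuous targets are quantized upward
  (`quantize_rheobase()`).
* **Spike threshold / amplitude** — means over all spikes at and above
  rheobase (averaging across suprathreshold sweeps reduces variance; a
  rheobase-sweep-only mode is available since the source convention is not
  stated).
* **I–V curve / cumulative spike number** — per-positive-level spike counts
  and their sum.

An invariance worth noting (and tested): adding a constant to every sample
changes only the resting potential — resistance, sag, counts are
difference-based.

## The mechanistic model

Voltages in mV, conductances nS, capacitance pF, time ms:

$$C \dot V = -g_L (V - E_L) - g_h\, h\, (V - E_h)
  + g_L \Delta_T e^{(V - V_T)/\Delta_T} + I(t),$$
$$\dot h = (h_\infty(V) - h)/\tau_h, \qquad
  h_\infty(V) = \frac{1}{1 + e^{(V - V_{1/2})/k_h}}.$$

When `V` reaches `V_peak` a spike is logged, `V` resets and integration
pauses for the refractory period. The EIF mechanism is the cheapest model
with a true rheobase and threshold kink — sufficient because the pipeline
analyzes features, not spike-shape biophysics. The h-gate activates under
hyperpolarization (`k_h > 0`), producing the depolarizing sag that the sag
extractors quantify; sag grows with `g_h` (tested over 0/2/4 nS).
Integration is fixed-step Euler on the recording grid with 4 internal
substeps (default 12.5 µs at 20 kHz), so outputs align with recorded
samples; the recorded sample of a spiking step is pinned at `V_peak` so the
waveform-level detector sees the same event the simulator logged. Diverging
trajectories raise an integration error advising a smaller step. Initial
state is the numerically solved subthreshold fixed point. Defaults
(`C = 150 pF`, `g_L = 10 nS`, `E_L = −65 mV`) give resting near −65 mV and
input resistance near 100 MΩ, in the range reported for CA1 pyramidal
cells. In the passive limit (`g_h = 0`, no noise) the measured resistance
matches `1/g_L` within 2% and resting matches `E_L` within 0.1 mV.

## sEPSC generation and detection

The generator places Poisson-timed biexponential kernels
$a\,(e^{-t/\tau_d} - e^{-t/\tau_r})/N$ (peak-normalized by `N`) as inward
(negative) deflections on the holding current — AMPA-mediated events at a
−70 mV holding potential are inward, while amplitudes are reported as
positive magnitudes, matching convention. The analytic charge per event is
$a(\tau_d - \tau_r)/N$ in fC (pA·ms). Amplitudes are lognormal; noise is
additive white Gaussian — the simplest model that exercises detector
robustness (colored noise is out of scope).

The detector (`detect_epsc_events()`, threshold 7 pA by convention):

1. baseline: 200-ms running median (robust to event density; configurable);
2. candidates: excursions of the 0.5-ms-boxcar-smoothed deflection below
   −threshold; the reported amplitude is the smoothed peak magnitude, whose
   attenuation is negligible for τ_rise ≥ 0.5 ms kernels while suppressing
   the positive noise bias a raw-sample peak would carry;
3. onset: last sample before the peak with deflection magnitude < 1 pA;
4. overlap resolution: consecutive peaks are separate events only when the
   trace recovers above 50% of the smaller magnitude between them. Applying
   this to *all* consecutive pairs (not only sub-5-ms doublets) is what
   keeps noise-induced minima along a decay tail from being counted as
   events; for genuinely distinct excursions the recovery to baseline
   always satisfies the criterion, so nothing is lost.
5. charge: trapezoidal integral of the raw deflection from onset until the
   first return to within 1 pA of baseline (or 100 ms — the cap prevents
   baseline-drift blowup), plus an exponential tail extrapolation
   `|s(t_off)|·τ̂`, with τ̂ fitted log-linearly over the last ~1 ms and
   gated to (0, 60] ms. Truncating at the 1 pA return alone loses ~4% of a
   20-pA event's charge; with the extrapolation, noiseless kernels recover
   the analytic charge well within 2%.

Events with amplitude below the threshold never appear in the output. The
summary reports the *median* per-event amplitude and charge (the
conventional wording is ambiguous between median and mean area; both are
available, median is the default for internal consistency) and the average
frequency = count/duration.

At the benchmark operating point (1 Hz, lognormal amplitudes with median
25 pA, 1.5 pA noise — amplitude SNR ≥ 5) the detector achieves recall and
precision ≥ 0.95, frequency within 10% and median amplitude within 5% of
the generating values; the residual recall loss is genuinely overlapping
event pairs.

## Field potentials and LTP

The generator gives the population spike a sigmoidal input–output relation
$A(S) = A_{max}/(1 + e^{-(S - S_{50})/k_S})$ and the fEPSP a linear slope
relation `epsp_gain · S`, with intensities below a stimulation threshold
evoking nothing and an exponential approach
$1 + (f - 1)(1 - e^{-\Delta t/\tau})$ to the potentiated level after TBS
(the TBS itself only marks the transition time; burst artifacts are not
synthesized). Measurement conventions:

* **POP-spike amplitude** — in a 3–40 ms post-stimulus window on the
  pyramidale channel: mean of the two positive flanking peaks minus the
  trough (the dominant hippocampal convention; a baseline-to-trough
  alternative is configurable), 0 unless the trough is deeper than 3× the
  pre-stimulus noise SD.
* **fEPSP initial slope** — chord between the 20% and 80% points of the
  rising phase, magnitude in mV/s (the closest operational reading of a
  slope "derived from amplitude and rising time"; a maximum-derivative
  alternative could be configured via the chord fractions).
* **Thresholds** — smallest tested intensity whose response exceeds 3× the
  pre-stimulus noise SD. One uniform detectability rule (3σ) is used
  throughout. For the EPSP channel the *amplitude* is compared against the
  noise SD — comparing a slope (mV/s) against a voltage SD (mV) would be
  dimensionally inconsistent.
* **70% calibration** — linear interpolation between the two tested
  intensities bracketing 0.7× the maximal POP-spike amplitude. A series
  still rising at its end (last increment > 5% of the maximum with the
  bracket in the final interval) warns and returns the top intensity.
* **LTP%** — 100 × (mean over the final 6-sweep bin of the follow-up) /
  (baseline mean), per channel; consistent with the 6-point binning used
  for time-course displays (`bin_timecourse()`, trailing partial bins
  flagged). A last-5-minutes window could be obtained via `final_bin`.
  LTP% is scale-invariant and symmetric for depression (factor 0.8 → 80%).

## Statistics

`summarize_group()` (mean, SEM with the n−1 SD), `one_way_anova()`,
`levene_test()` (classic mean-centered by default; Brown–Forsythe by flag)
and `tukey_hsd()` (Tukey–Kramer for unbalanced groups) delegate to the
standard fitters (`stats::aov`, `stats::TukeyHSD`, `car::leveneTest`) and
own the degenerate cases: identical data give an undefined F (absent); zero
within-group variance with unequal means gives p = 0. Levene's result is
reported, never used to switch tests automatically (no fallback procedure
is prescribed). `compare_groups()` assembles the publication-style row
(mean ± SEM with stars at 0.05/0.01/0.001). The module runs the omnibus
over whatever labels the design names; the conventional reading — pairwise
control vs treated within one sex and age — is the two-label case, where
the Tukey-adjusted p equals the omnibus p (identity tested to 1e−6) and
F = t² against the pooled t test. The type-I star rate at the 0.05 level is
5% ± 1.5% over 2,000 null comparisons. The repeated-measures ANOVA
sometimes applied to LTP time courses is out of scope (no reference results
exist to verify against).

## Cohort designs and reference values

`reference_group_values()` stores published group summaries (mean, SEM, n)
for the eight sex × age × treatment groups — intrinsic, sEPSC and
field-potential parameters of the VPA rat CA1 dataset — as realistic
generator targets. Published tables give mean ± SEM only, not per-cell
distributions, so cohort SDs are reconstructed as SEM·√n (assuming the
printed n applies per parameter) and cells are drawn from independent
Gaussians (`generate_cohort()`); rheobase draws are quantized upward to the
protocol grid, and the cumulative spike number is distributed over
suprathreshold levels as a non-decreasing count ramp (`make_iv_curve()`).
What passing tests show is therefore calibration of the *machinery* —
extraction exactness, detector operating characteristics, statistical
level and power — not biological realism of cell-to-cell covariance,
correlated parameters, drift, or seal-quality artifacts, which the
generator deliberately does not model.

## Problem sizes and numerical choices

Exactness of the parametric round trip is independent of the sampling rate
and level grid by construction, so test and benchmark runs choose sizes
deliberately:

* exact-recovery checks run on the full acquisition protocol (5 pA grid,
  20 kHz);
* sEPSC benchmarks run 200-s traces at 10 kHz sampling (the EPSC hardware
  bandwidth being 2.5 kHz, this is still 2× oversampled);
* cohort power runs (2 × 50 cells, 100 effect and 100 null replicates in
  the test suite) use a 20 pA grid at 1 kHz, where rheobase quantization
  noise (±20 pA uniform) is small against the reconstructed group SDs
  (~50 pA).

Other numerical choices: epochs are half-open sample-index intervals
(no off-by-one ambiguity at boundaries); canonical units (mV, pA, MΩ, fC,
s, Hz, V) everywhere inside the package with conversion only at the I/O
boundary; sidecar-declared hardware filtering is kept as provenance text
and never re-applied (the data were filtered in hardware once — re-filtering
synthetic data would double-apply); trace files are written with 17
significant digits so read∘write is the identity; one sweep per protocol
level (repetition counts are not part of the format).

## Known limitations

* The spike-shape constants are conventions, not fits; pathological
  waveforms (e.g. plateau potentials) would need retuning via
  `spike_config()`.
* The EPSC detector assumes a stationary baseline at the 200-ms scale;
  faster drift biases charge despite the running median.
* The mechanistic neuron is single-compartment and omits adaptation,
  IPSCs/GABAergic conductances and dendritic filtering.
* Event detection near trace edges (within one baseline window) is less
  reliable; the generator keeps events away from the final 150 ms.
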
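---
title: "Feeding microstructure and calcium transients: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feeding microstructure and calcium transients: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flicmeal)
```

## The measurement problem

A capacitive fly-to-liquid-food interaction counter (FLIC) reports one
arbitrary-unit signal per channel every 200 ms; a fly touching the liquid
food raises the signal above the channel's slowly drifting electrical
baseline. Everything downstream of the raw signal — meals, bouts, feeding
rates, satiation times — is a function of how that excess is thresholded
and aggregated. This package implements one explicit, fully parameterized
version of that chain, together with a closed-loop optogenetic trigger
model and ΔF/F₀ transient metrics for stimulus-locked fluorescence traces,
and a synthetic-data generator with exact ground truth so every stage can
be verified end to end.

## From raw signal to meals

**Baseline.** The baseline is a centered rolling *median*
(`moving_baseline()`, window `window_s = 120` s by default, truncated at
the trace edges). A median is the right location estimate here because
food interactions are brief one-sided positive excursions: a rolling mean
absorbs them into the baseline and suppresses subsequent detections, while
the median ignores them as long as in-bout samples stay a minority of the
window (at 5 Hz and realistic bout rates they are a few percent).
Interior windows use the O(n log k) Turlach running-median; the shrinking
edge windows are computed directly.

**Detection.** Sample *i* is a *food interaction* when
`signal[i] − baseline[i] > threshold`, strictly. The strict inequality and
the default `threshold = 10` AU mirror the closed-loop trigger rule
("every food interaction signal over 10"); the offline analysis threshold
and baseline window of the original rig software are configuration here,
surfaced in `flic_analysis_params()`, because they are implementation
choices of that software rather than published constants.

**Binning and days.** Interactions are summed in half-open 30-min bins
anchored at the experiment start (`bin_interactions()`), and days are
contiguous 24 h windows from the same anchor (`split_days()`). The rig
runs in constant darkness (to avoid ambient activation of the opsin), so
there is no lights-on edge to anchor to; the day boundary is configuration
(`day_offset_s`).

**Meals.** A meal (`segment_meals()`) is a maximal run of bins whose
count reaches `max(1, ceiling(min_frac × day-max))`, tolerating up to
`gap_bins` consecutive sub-threshold bins inside the run (defaults
`min_frac = 0.1`, `gap_bins = 1`). A relative-to-day-max criterion adapts
to flies with very different overall activity; both knobs are logged
output, not hidden constants. The meal peak is the earliest bin with the
maximal count — a deterministic tie-break that also makes latency-type
metrics reproducible. All meal-based metrics use the *evening* meal
(`select_evening_meal()`): the meal whose peak falls in the subjective
evening window (default hours 9–15 after the day anchor, configurable),
largest first, earliest on ties; when no meal peaks in the window the
day's largest meal is used and flagged as a fallback rather than silently
substituted.

**Metrics.** With the peak placed at the *start* of the peak bin,
`meal_metrics()` reports `duration_h = pre_peak_h + post_peak_h` exactly;
post-peak duration (meal end − meal peak) is the satiation proxy. Feeding
*events* (bouts, `extract_events()`) are maximal runs of consecutive
interaction samples — one sub-threshold sample ends a bout, matching
"consecutive" literally — assigned to a meal by their start time in the
half-open meal interval. The feeding rate is events per meal divided by
meal duration. For the pre/post-peak split (`split_rate_at_peak()`) the
boundary is the *end* of the peak bin: events "before and including the
peak" and the peak bin's full width both count as pre-peak, so each side's
rate divides a count by the time that produced it. (This makes the split
durations differ from `pre_peak_h`/`post_peak_h` by one bin width; the
two conventions serve different metrics and are both reported.)

## The closed-loop controller

`run_controller()` emits a light train for every sample whose excess over
baseline is strictly above the trigger threshold, on or after
`start_day = 3` (days are 1-based; the first two days record baseline
feeding). A train is 200 ms of ~627 nm light pulsing at 60 Hz with 4 ms
pulses — 12 pulses, onsets exactly 1/60 s apart. Triggers arriving while
a train is in progress are absorbed and counted, since overlapping trains
are physically meaningless on one LED; at the FLIC's 200 ms sample period
the train ends exactly as the next sample arrives, so in practice nothing
is absorbed. The controller is causal by construction. Retinal status is
a property of the simulated fly: without dietary all-trans-retinal the
opsin is non-functional and light has no effect, which is exactly the
−ATR control arm.

## ΔF/F₀ transient metrics

`compute_dff()` uses F₀ = mean of the 10 frames immediately before the
stimulus frame (frame period 0.254 s) and returns fractions; the % scale
is presentation. The response window (`detect_response_window()`) is
defined by a k·σ rule because "initiation" and "end" of a response need
an operational definition: the window starts at the first post-stimulus
frame with ΔF/F₀ above `k_sigma = 2` baseline SDs and ends at the last
frame before the trace falls back to or below that level after the peak
(or the last frame). Peak is the single in-window maximum (earliest frame
on ties, so latency is deterministic); latency is (peak frame − stimulus
frame) × frame period and is always a frame multiple; AUC is the plain
sum of in-window ΔF/F₀ values, with a time-weighted variant
(`time_weighted = TRUE`) behind a flag since both conventions exist in
practice.

## What the generator emulates — and what it does not

`sim_config()` defaults *are* the emulated study conditions: 20 flies ×
10 days at 5 Hz, one channel per fly, one evening meal per day centered
at subjective hour 12. Within the meal, per-bin bout counts follow an
inhomogeneous profile (a 3-bin ramp, a peak bin, and a tail decaying
toward a floor), bouts have geometric lengths (mean 5 samples = 1 s), and
per-sample excursions are uniform on 25–60 AU. Per-fly lognormal effects
(σ_log = 0.15) model well-to-well variability. On the sugar diet the
in-meal intensity grows ×1.10 per day and the post-peak tail lengthens
linearly so that day 10 exceeds day 1 by ≈ 4 h of post-peak feeding —
the magnitudes reported for chronic high-sugar exposure. With closed-loop
light and retinal, both growth factors clamp at the first triggered day's
value (light starts day 3), reproducing the opto-stabilized arm; without
retinal the generator behaves like plain sugar diet.

Two deliberate simplifications matter when interpreting green tests:

* **Per-bin bout counts are shifted Poisson** (1 + Poisson(λ−1)), so
  every in-meal bin contains at least one bout. This gives meals hard
  boundaries in bin space, which is what makes *exact* ground-truth
  recovery a meaningful contract; real meals have soft edges, and real
  boundary recovery is necessarily approximate. Relatedly, exactness is
  claimed under generator-matched analysis settings
  (`recovery_analysis_params()`, `min_frac` small enough that the bin
  threshold is one interaction); the generic `min_frac = 0.1` default can
  exceed the guaranteed one-count floor on high-activity days.
* **Baseline drift is a bounded random walk** (±2.5 AU, below 30% of the
  detection threshold) and bouts are placed in disjoint slots with at
  least one quiet sample between them, so detection and bout extraction
  are exact by construction. Real FLIC data contain leg events, grooming
  artifacts and drift excursions the generator does not model; passing
  recovery tests demonstrate the pipeline's correctness, not robustness
  to those artifacts (raise `drift_bound` for stress testing).

Inside the simulator the trigger rule is evaluated against the *known*
drift — the hardware thresholds online against its own running estimate —
while the analysis path always re-estimates the baseline from the signal.

Calcium transients are a peak-normalized, peak-aligned rise-decay
double-exponential (τ_r = 0.2 s, τ_d = 1.0 s), so the noiseless trace
peaks at exactly the configured latency with exactly the configured
amplitude: recovered-vs-true comparisons need no deconvolution. Sugar
diet halves the sucrose amplitude (×0.5) and delays the peak by 0.6 s;
water responses are diet-independent; noise SD is 0.06 ΔF/F₀ (SNR > 8).
Because latency is read off a 0.254 s frame grid, individual recovered
latencies quantize to frame multiples and the honest recovery summary is
the median error, which stays well within one frame at default SNR.

## Statistics

`mann_whitney_u()` fronts the rank-sum test with the conventions used in
the figure-level analyses: midrank ties; exact enumeration when the
combined n ≤ 12 with no ties, otherwise the normal approximation with tie
and continuity corrections; identical-value degeneracy returns p = 1 with
a flag. The repeated-measures interaction test is replaced by
`interaction_permutation_test()`: fly means are removed, the statistic is
the interaction sum of squares of group × day cell means, and the null
permutes group labels across whole flies — preserving each fly's
within-subject correlation while assuming exchangeability of flies
between groups, which is the design's randomization. p = (1 + #{perm ≥
obs}) / (1 + n_perm) keeps the test valid at finite n_perm. Day-10 versus
day-3 contrasts use one-sided sign tests (`sign_test_increase()`), ties
dropped. No multiplicity correction is applied across metrics, matching
the figure-by-figure reporting convention.

## Problem sizes and numerical choices

The test suite runs the oracle-equivalence checks on 1,000 random bout
vectors (up to 10⁵ samples) and brute-force baseline recomputation on
traces up to 2,000 samples; meal identities on 50 seeded one-fly
experiments; exact recovery and the three-condition contrast on the full
20 flies × 10 days per condition; calcium recovery on 100 seeded
transients plus 40 replicates of 30-ROI group comparisons; and 200
additive-null datasets for the permutation test's type-I calibration.
Time comparisons use a 1e-9 s tolerance wherever half-open boundaries
meet floating-point clocks; bin widths must be integer multiples of the
sample period for the same reason. All generators are deterministic given
a seed, with per-fly seeds derived from the experiment seed.

## Limitations

The pipeline does not distinguish proboscis from leg contacts, model the
capacitance electronics, fit circadian structure, convert events to
ingested volume, or infer spikes from calcium; the generator makes no
attempt to fit the original raw data (which are not deposited) and its
effect-size defaults are the published approximate magnitudes, chosen so
the qualitative figures regenerate with known truth.
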
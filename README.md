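# flicmeal

Feeding-microstructure and stimulus-locked calcium-trace analysis for
*Drosophila* feeding experiments on capacitive monitors (FLIC —
fly-to-liquid-food interaction counter), including the closed-loop
optogenetic ("optoFLIC") trigger protocol and a synthetic-data generator
with exact ground truth.

It is written for researchers who record feeding as a 5 Hz capacitance
signal per fly and need the full chain from raw signal to interpretable
meal metrics, and for anyone analyzing stimulus-locked ΔF/F₀ transients
(GCaMP or pHluorin) with peak / latency / AUC readouts.

## What it computes

**Feeding.** For a raw per-channel signal *x(t)* sampled every 200 ms:

- baseline *b(t)*: centered rolling median (default 120 s window);
- food interactions: samples with *x(t) − b(t) > θ* (strict; default
  θ = 10 AU), summed in half-open 30-min bins;
- meals: maximal runs of bins above a day-relative count threshold, with
  gap tolerance; the evening meal (peak in subjective hours 9–15) is used
  for all meal metrics;
- meal metrics: size (interactions), duration, pre-peak and post-peak
  duration (satiation proxy), with `duration = pre + post` exactly;
- feeding events (bouts): maximal runs of consecutive interaction
  samples; feeding rate = events / duration, also split before-vs-after
  the meal peak.

**Closed-loop opto.** Every interaction signal over the trigger
threshold from day 3 onward emits a 200 ms train of 60 Hz light pulses
(12 pulses × 4 ms); trains never overlap and the controller is causal.

**Calcium.** ΔF/F₀ against the mean of the 10 pre-stimulus frames
(0.254 s/frame); response window by a 2σ baseline-noise crossing; peak
ΔF/F₀, latency-to-peak, and summed AUC.

**Statistics.** Mann-Whitney U (exact for small tie-free samples), a
whole-fly permutation test for time-by-treatment interactions in
repeated-measures designs, and one-sided sign tests for paired day
contrasts.

**Synthetic data.** `sim_config()` / `simulate_fly()` generate raw
FLIC-style traces with known meal boundaries, bout counts and interaction
counts for three conditions — sugar diet (meals grow daily; post-peak
duration lengthens ≈ 4 h by day 10), sugar diet + feeding-triggered light
with retinal (growth clamps from day 3), and light without retinal
(behaves like sugar diet). `simulate_calcium_trace()` generates
transients whose sucrose response is halved and delayed 0.6 s on a sugar
diet, with diet-independent water responses.

## Worked example

```r
library(flicmeal)

cfg <- sim_config(n_flies = 1, n_days = 3, diet = "SD", seed = 42)
sim <- simulate_fly(cfg, 1)
res <- analyze_flic_trace(sim$trace, recovery_analysis_params())
res$per_day[, c("day", "daily_interactions", "meal_size",
                "events_per_meal", "duration_h", "post_peak_h")]
#>   day daily_interactions meal_size events_per_meal duration_h post_peak_h
#> 1   1                355       355              84        5.0         3.5
#> 2   2                544       544             113        7.0         5.0
#> 3   3                800       800             156        9.0         7.5
```

One simulated fly on a sugar diet: the evening meal grows from 355 to
800 interactions in three days, the meal lengthens from 5 to 9 h, and the
post-peak (satiation) phase from 3.5 to 7.5 h — and every recovered
boundary, interaction count and bout count equals the generator's ground
truth exactly (`sim$truth`).

The numbered scripts under `analysis/` run the full study-scale workflow
(simulate the three feeding conditions; signal → microstructure; opto
rescue statistics; calcium metrics; report bundle), writing tidy CSVs
under `results/`. On defaults the sugar-diet arm lengthens post-peak
feeding by ≈ 4 h over 10 days and the retinal-fed closed-loop arm stays
flat, with the time-by-retinal interaction at the permutation floor
(p ≈ 0.001); the calcium contrast gives a ~48 % sucrose peak decrease and
a ~0.8 s latency delay with unchanged water responses.

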
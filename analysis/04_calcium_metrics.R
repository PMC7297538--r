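#!/usr/bin/env Rscript
# Stimulus-locked transient analysis: simulate per-ROI sucrose and water
# responses for control- and sugar-diet flies (30 ROIs/group), compute
# dF/F0 peak, latency-to-peak and AUC, and compare diets with the
# Mann-Whitney test. Writes per-ROI metrics and test results.

library(flicmeal)

seed <- 5150
dir.create("results", showWarnings = FALSE)
p <- ca_sim_params()
n_roi <- 30

rows <- list()
for (diet in c("CD", "SD")) for (stim in c("sucrose", "water")) {
  for (i in seq_len(n_roi)) {
    sim <- simulate_calcium_trace(p, diet, stim,
                                  seed = seed + i +
                                    1000 * match(diet, c("CD", "SD")) +
                                    2000 * match(stim, c("sucrose", "water")),
                                  roi_id = sprintf("%s_%s_%02d", diet, stim, i))
    m <- trace_metrics(compute_dff(sim$trace))
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(diet = diet, stimulus = stim, roi = sim$trace$roi_id),
      m, true_amplitude = sim$truth$amplitude,
      true_latency_s = sim$truth$latency_s)
  }
}
ca <- do.call(rbind, rows)
write.csv(ca, "results/calcium_metrics.csv", row.names = FALSE)

pick <- function(diet, stim, col)
  ca[ca$diet == diet & ca$stimulus == stim, col]
tests <- do.call(rbind, lapply(c("sucrose", "water"), function(stim) {
  mw_peak <- mann_whitney_u(pick("CD", stim, "peak_dff"),
                            pick("SD", stim, "peak_dff"))
  mw_lat <- mann_whitney_u(pick("CD", stim, "latency_s"),
                           pick("SD", stim, "latency_s"))
  data.frame(stimulus = stim,
             cd_peak = median(pick("CD", stim, "peak_dff")),
             sd_peak = median(pick("SD", stim, "peak_dff")),
             p_peak = mw_peak$p,
             cd_latency_s = median(pick("CD", stim, "latency_s")),
             sd_latency_s = median(pick("SD", stim, "latency_s")),
             p_latency = mw_lat$p)
}))
print(tests, digits = 3)
write.csv(tests, "results/calcium_tests.csv", row.names = FALSE)
cat(sprintf(
  "Sucrose: SD peak is %.0f%% below CD and peaks %.2f s later; water unchanged.\n",
  100 * (1 - tests$sd_peak[1] / tests$cd_peak[1]),
  tests$sd_latency_s[1] - tests$cd_latency_s[1]))
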
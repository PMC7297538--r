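#!/usr/bin/env Rscript
# Bundle the feeding and calcium tables plus test results into one report
# directory with run metadata.

library(flicmeal)

feeding <- read.csv("results/feeding_metrics_sd.csv")
calcium <- read.csv("results/calcium_metrics.csv")
opto <- read.csv("results/opto_rescue_tests.csv")
ca_tests <- read.csv("results/calcium_tests.csv")

tests <- rbind(
  data.frame(test = "sign_day10_vs_day3_sd", groups = "SD",
             n = 20, statistic = NA, p = opto$p_sd,
             method = paste0("sign:", opto$metric)),
  data.frame(test = "mw_peak_cd_vs_sd", groups = ca_tests$stimulus,
             n = 60, statistic = NA, p = ca_tests$p_peak,
             method = "mann_whitney"))

rep_ <- build_report(feeding, calcium, tests,
                     params = list(seed_feeding = 2026, seed_ca = 5150,
                                   threshold = 10, baseline_window_s = 120,
                                   bin_width_s = 1800),
                     dir = "results/report")
print(rep_)
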
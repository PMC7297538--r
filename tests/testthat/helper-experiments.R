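# Memoized full-scale experiment runs shared by the acceptance blocks
# (each condition is simulated and analyzed once per test session).

.exp_cache <- new.env(parent = emptyenv())

full_experiment <- function(opto, diet = "SD", seed = 101) {
  key <- paste(diet, opto, seed, sep = "_")
  if (is.null(.exp_cache[[key]])) {
    cfg <- sim_config(n_flies = 20, n_days = 10, diet = diet, opto = opto,
                      seed = seed)
    .exp_cache[[key]] <- analyze_flic_experiment(cfg,
                                                 recovery_analysis_params())
  }
  .exp_cache[[key]]
}

day_contrast <- function(metrics, col, day_hi = 10, day_lo = 3) {
  hi <- metrics[metrics$day == day_hi, ]
  lo <- metrics[metrics$day == day_lo, ]
  hi <- hi[order(hi$fly), ]
  lo <- lo[order(lo$fly), ]
  list(after = hi[[col]], before = lo[[col]])
}
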
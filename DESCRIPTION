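Package: flicmeal
Title: Feeding Microstructure and Stimulus-Locked Calcium Trace Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for capacitive fly-to-liquid-food
    interaction counter (FLIC) recordings and stimulus-locked fluorescence
    traces. Detects food interactions above a moving-median baseline, bins
    them, segments meals and feeding events (bouts), and computes meal
    microstructure metrics (size, duration, peak time, pre-/post-peak
    durations and feeding rates). Simulates the closed-loop optogenetic
    trigger protocol (feeding-triggered 200 ms, 60 Hz light trains) and
    provides delta-F/F0 transient metrics (peak, latency-to-peak, AUC) for
    calcium traces. Includes synthetic-data generators with ground truth
    emulating control-diet, sugar-diet and opto-rescued feeding dynamics,
    plus rank-based and permutation group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
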
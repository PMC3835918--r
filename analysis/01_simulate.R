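#!/usr/bin/env Rscript
# Generate one synthetic bead-array experiment under the study design:
# 2 tumor types x 3 patients x 2 sites x 4 delays to cryopreservation
# (5/15/30/120 min), with a small fraction of genuinely time-dependent
# probes, and write the expression/control/metadata files plus the ground
# truth that downstream stages are checked against.

suppressMessages(library(warmclock))

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
cfg <- sim_config(n_probes = 8000, seed = 20260926L)
sim <- simulate_dataset(cfg)

write_expression(sim$data,
                 "results/data/expression.tsv",
                 "results/data/negative_controls.tsv",
                 "results/data/samples.csv")
write_ground_truth(sim$truth, "results/data/ground_truth.tsv")

n_trend <- sum(sim$truth$probes$is_trend)
cat("simulated", nrow(sim$data$signal), "probes x",
    ncol(sim$data$signal), "samples;", n_trend,
    "probes carry a genuine time trend at",
    cfg$trend_rate_pct_per_hr, "%/hr\n")
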
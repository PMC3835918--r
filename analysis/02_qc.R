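#!/usr/bin/env Rscript
# Pre-normalization quality control: detection calls against negative
# controls, per-sample detected-gene counts and their Poisson model,
# P95/P05 signal-strength ratios, the RIN-on-time regression, and
# central/peripheral correlation. Writes a Table-1-style per-sample QC
# table plus the model coefficient tables.

suppressMessages(library(warmclock))

es <- read_expression("results/data/expression.tsv",
                      "results/data/negative_controls.tsv",
                      "results/data/samples.csv")
qc <- qc_report(es, array_effects = "fixed")

write_results(list(
  qc_samples = qc$samples,
  detection_count_model = qc$detection_count_model,
  central_peripheral_r2 = qc$central_peripheral_r2,
  rin_regression = data.frame(qc$rin_regression)
), "results/qc")

cat(sprintf("P95/P05: %d/%d samples pass (>10); detected genes %d-%d\n",
            sum(qc$samples$pass_p95p05), nrow(qc$samples),
            min(qc$samples$detected_genes), max(qc$samples$detected_genes)))
cat(sprintf("RIN vs time: slope %.3f/hr (p = %.2f); median c/p r2 = %.3f\n",
            qc$rin_regression$slope_per_hr, qc$rin_regression$p,
            median(qc$central_peripheral_r2$r2)))
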
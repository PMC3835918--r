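#!/usr/bin/env Rscript
# Unsupervised sample clustering (centred correlation, average linkage),
# fold-change outlier counts against the 5-minute reference, and the
# aggregated run report (all tables + newick dendrogram).

suppressMessages(library(warmclock))

es <- read_expression("results/data/expression.tsv",
                      "results/data/negative_controls.tsv",
                      "results/data/samples.csv")
qc <- qc_report(es, array_effects = "fixed")
ns <- normalize_matrix(es, qc$detection_pvals)

dend <- hierarchical_cluster(ns$log_expr)
cl <- cut_dendrogram(dend, k = 2)
ri <- rand_index(unname(cl), as.integer(factor(ns$samples$tumor_type)))
cat(sprintf("top dendrogram split vs tumor type: Rand index %.3f\n", ri))

fc <- fold_change_outliers(ns$log_expr, ns$samples)
cat("mean >2-fold outliers vs t5, by time (min):\n")
print(round(tapply(fc$n_outliers, fc$time_min, mean), 1))

flt_keep <- ns$filter_log$status == "kept"
le <- log_transform(es$signal[flt_keep, ])
trend <- overall_trend_table(le, es$samples)

sig <- list()
for (tt in unique(es$samples$tumor_type)) {
  keep <- es$samples$tumor_type == tt
  sub <- es
  for (f in c("signal", "negatives", "bead_sd")) {
    sub[[f]] <- sub[[f]][, keep, drop = FALSE]
  }
  sub$samples <- sub$samples[keep, , drop = FALSE]
  nst <- normalize_matrix(sub)
  sig[[tt]] <- significant_genes(fit_timecourse(nst$log_expr, nst$samples),
                                 nst$probes)
}

fits <- fit_timecourse(ns$log_expr, ns$samples)
truth <- read_ground_truth("results/data/ground_truth.tsv")
trend_genes <- intersect(unique(es$probes$symbol[truth$is_trend]),
                         ns$probes$symbol)
ney <- geneset_neyman(fits, ns$probes, trend_genes, set_name = "trend_genes")

build_report(list(qc = qc, overall_trend = trend, significant_genes = sig,
                  geneset_neyman = ney, geneset_consistency = NULL,
                  dendrogram = dend, fold_change = fc),
             "results/report")
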
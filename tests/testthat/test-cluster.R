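test_that("correlation distances match hand computation and merge order", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1),
             d = c(1.1, 2, 3, 4.2))
  dend <- hierarchical_cluster(m)
  dm <- as.matrix(dend$dist)
  expect_equal(dm["a", "b"], 0, tolerance = 1e-12)  # perfectly correlated
  expect_equal(dm["a", "c"], 2, tolerance = 1e-12)  # r = -1 -> distance 2
  # the identical pair merges first
  first <- dend$hclust$merge[1, ]
  expect_setequal(dend$hclust$labels[-first], c("a", "b"))
  expect_true(all(diff(dend$hclust$height) >= -1e-12))
  m[, "d"] <- 5
  expect_error(hierarchical_cluster(m), "d")
})

test_that("dendrogram leaves are stable under sample input order", {
  set.seed(12)
  m <- matrix(rnorm(100 * 8), 100, 8,
              dimnames = list(NULL, paste0("s", 1:8)))
  d1 <- hierarchical_cluster(m)
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  d2 <- hierarchical_cluster(m[, perm])
  c1 <- cut_dendrogram(d1, k = 3)
  c2 <- cut_dendrogram(d2, k = 3)[names(c1)]
  expect_equal(rand_index(c1, c2), 1)
})

test_that("a dominant tumor-type effect splits the dendrogram by type", {
  sim <- simulate_dataset(small_config(n_probes = 1200, seed = 33L))
  ns <- suppressMessages(normalize_matrix(sim$data))
  dend <- hierarchical_cluster(ns$log_expr)
  cl <- cut_dendrogram(dend, k = 2)
  type <- as.integer(factor(ns$samples$tumor_type))
  expect_equal(rand_index(unname(cl), type), 1)
})

test_that("newick export round-trips through ape", {
  set.seed(2)
  m <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(NULL, paste0("s", 1:6)))
  dend <- hierarchical_cluster(m)
  txt <- dendrogram_newick(dend)
  phy <- ape::read.tree(text = txt)
  expect_setequal(phy$tip.label, paste0("s", 1:6))
  f <- withr::local_tempfile(fileext = ".nwk")
  dendrogram_newick(dend, f)
  expect_identical(readLines(f), txt)
})

test_that("fold-change outliers count constructed 2-fold exceedances", {
  es <- tiny_expr_set(10)
  le <- suppressMessages(log_transform(es$signal))
  # make t120 of the central series exceed 2-fold for exactly 3 probes
  i120 <- which(es$samples$time_min == 120 & es$samples$site == "central")
  i5 <- which(es$samples$time_min == 5 & es$samples$site == "central")
  le[, i120] <- le[, i5]
  le[1:3, i120] <- le[1:3, i5] + log(2.1)
  le[4, i120] <- le[4, i5] + log(1.9) # below the cutoff
  fc <- fold_change_outliers(le, es$samples)
  central <- fc[fc$series == "HCC.HCC1.central", ]
  expect_equal(central$n_outliers[central$time_min == 5], 0)
  expect_equal(central$n_outliers[central$time_min == 120], 3)
  # inverting ratios leaves counts unchanged
  le2 <- le
  le2[, i120] <- 2 * le2[, i5] - le[, i120]
  fc2 <- fold_change_outliers(le2, es$samples)
  expect_equal(fc2$n_outliers, fc$n_outliers)
})

test_that("outlier counts grow with time gap for a decaying signature", {
  sim <- simulate_dataset(small_config(n_probes = 2000, seed = 44L))
  genes <- unique(sim$data$probes$symbol[sim$truth$probes$expressed])[1:40]
  inj <- inject_signature(sim$data, genes, -60)
  ns <- suppressMessages(normalize_matrix(inj))
  fc <- fold_change_outliers(ns$log_expr, ns$samples)
  m15 <- mean(fc$n_outliers[fc$time_min == 15])
  m120 <- mean(fc$n_outliers[fc$time_min == 120])
  expect_gt(m120, m15)
})

test_that("build_report writes every section deterministically", {
  sim <- simulate_dataset(small_config(n_probes = 1500, seed = 27L))
  es <- sim$data
  qc <- suppressMessages(qc_report(es, array_effects = "fixed"))
  ns <- suppressMessages(normalize_matrix(es, qc$detection_pvals))
  keep <- ns$filter_log$status == "kept"
  le_all <- suppressMessages(log_transform(es$signal[keep, ]))
  trend <- suppressWarnings(overall_trend_table(le_all, es$samples))
  sig <- list()
  for (tt in c("HCC", "LC")) {
    sel <- ns$samples$tumor_type == tt
    fits <- fit_timecourse(ns$log_expr[, sel], ns$samples[sel, ])
    sig[[tt]] <- significant_genes(fits, ns$probes)
  }
  fits_all <- fit_timecourse(ns$log_expr, ns$samples)
  set <- unique(ns$probes$symbol)[1:12]
  ney <- geneset_neyman(fits_all, ns$probes, set, set_name = "demo")
  pooled <- pool_gene_rates(fits_all, ns$probes)
  calls <- data.frame(gene_symbol = rep(set, 2),
                      study_id = paste0("s", 1:24),
                      direction = rep(c("up", "down"), each = 12),
                      stringsAsFactors = FALSE)
  cons <- suppressWarnings(suppressMessages(
    direction_consistency(pooled, calls)))
  results <- list(qc = qc, overall_trend = trend, significant_genes = sig,
                  geneset_neyman = ney, geneset_consistency = cons,
                  dendrogram = hierarchical_cluster(ns$log_expr),
                  fold_change = fold_change_outliers(ns$log_expr, ns$samples))
  dir <- withr::local_tempdir()
  paths <- suppressMessages(build_report(results, dir))
  expect_setequal(
    basename(paths),
    c("qc_samples.tsv", "overall_trend.tsv", "significant_genes.tsv",
      "geneset_neyman.tsv", "geneset_consistency.tsv",
      "consistency_genes.tsv", "fold_change.tsv", "dendrogram.nwk"))
  snapshot <- lapply(paths, readLines)
  paths2 <- suppressMessages(build_report(results, dir))
  expect_identical(lapply(paths2, readLines), snapshot)
  # missing stage errors by name
  expect_error(suppressMessages(build_report(results[-2], dir)), "trend")
  # single-type run: the other type marked absent, no crash
  results$significant_genes <- list(HCC = NULL, LC = sig$LC)
  paths3 <- suppressMessages(build_report(results, dir))
  sg <- read.delim(file.path(dir, "significant_genes.tsv"))
  expect_true("absent" %in% sg$direction)
})
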
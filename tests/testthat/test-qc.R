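test_that("detection p-values match the add-one exceedance oracle", {
  set.seed(101)
  es <- tiny_expr_set(20)
  es$negatives <- matrix(runif(50 * 8, 50, 150), 50, 8)
  es$signal <- matrix(runif(20 * 8, 40, 200), 20, 8,
                      dimnames = dimnames(es$signal))
  p <- detection_pvalues(es)
  N <- nrow(es$negatives)
  for (s in c(1, 4, 8)) {
    oracle <- (1 + colSums(outer(es$negatives[, s], es$signal[, s], ">="))) /
      (N + 1)
    expect_equal(unname(p[, s]), unname(oracle), tolerance = 0)
  }
})

test_that("detection p-values hit the closed-form extremes and are monotone", {
  es <- tiny_expr_set(3)
  N <- nrow(es$negatives) # all negatives equal 90
  es$signal[1, ] <- 10    # below every control
  es$signal[2, ] <- 1e6   # above every control
  es$signal[3, ] <- 90    # ties count as exceeding
  p <- detection_pvalues(es)
  expect_true(all(p[1, ] == 1))
  expect_equal(unname(p[2, ]), rep(1 / (N + 1), 8))
  expect_true(all(p[3, ] == 1))
  # monotone non-increasing in signal within a sample
  set.seed(7)
  es$negatives <- matrix(runif(60 * 8, 50, 150), 60, 8)
  sig <- matrix(sort(runif(24, 10, 300)), 3, 8)
  es$signal <- matrix(sig, 3, 8, dimnames = dimnames(es$signal))
  p <- detection_pvalues(es)
  for (s in 1:8) {
    ord <- order(es$signal[, s])
    expect_true(all(diff(p[ord, s]) <= 0))
  }
  es$negatives <- es$negatives[0, , drop = FALSE]
  expect_error(detection_pvalues(es), "negative controls")
})

test_that("genes are counted as detected under the any-probe rule", {
  p <- matrix(1, 4, 2, dimnames = list(NULL, c("s1", "s2")))
  symbols <- c("G1", "G1", "G1", "G2")
  # one of G1's three probes detected in s1 only
  p[2, 1] <- 0.001
  counts <- detected_gene_counts(p, symbols)
  expect_equal(unname(counts), c(1L, 0L))
  # all probes detected -> count = number of distinct genes
  counts <- detected_gene_counts(matrix(0.001, 4, 2), symbols)
  expect_equal(unname(counts), c(2L, 2L))
})

test_that("detected counts on mixed data sit between background and full", {
  sim <- simulate_dataset(small_config(n_probes = 3000, seed = 9L))
  pv <- detection_pvalues(sim$data)
  counts <- detected_gene_counts(pv, sim$data$probes$symbol)
  n_genes <- length(unique(sim$data$probes$symbol))
  expressed_genes <- length(unique(
    sim$data$probes$symbol[sim$truth$probes$expressed]))
  # bracket: more than nothing, no more than the expressed genes plus the
  # ~1% false-positive detection among background genes
  expect_true(all(counts > 0.02 * n_genes))
  expect_true(all(counts <= expressed_genes + ceiling(0.05 * n_genes)))
})

test_that("P95/P05 follows linear-interpolation percentiles and threshold", {
  const <- p95_p05_ratio(rep(5, 50))
  expect_equal(const$ratio, 1)
  expect_false(const$pass)
  # oracle: quantile type 7 on 1..100 -> 95.05 / 5.95
  r <- p95_p05_ratio(1:100)
  expect_equal(r$ratio, 95.05 / 5.95, tolerance = 1e-12)
  expect_true(r$pass)
  # scale invariance
  r2 <- p95_p05_ratio(3.7 * (1:100))
  expect_equal(r2$ratio, r$ratio, tolerance = 1e-12)
  # classification around the 10 cutoff
  expect_false(p95_p05_ratio(c(rep(1, 5), rep(9.51, 95)))$pass)
  expect_error(p95_p05_ratio(c(-1, 0, 1, 2)), "positive")
})

test_that("RIN regression recovers exact trends and handles degeneracy", {
  sm <- design_table()
  sm$rin <- 8 - 0.5 * sm$time_min / 60
  fit <- rin_time_regression(sm)
  expect_equal(fit$slope_per_hr, -0.5, tolerance = 1e-10)
  expect_lt(fit$p, 1e-12)
  # constant RIN: slope 0, p reported as 1
  sm$rin <- 7
  fit <- rin_time_regression(sm)
  expect_equal(fit$slope_per_hr, 0)
  expect_equal(fit$p, 1)
  # missing RIN dropped, error below 3 usable rows
  sm$rin <- c(7, 8, NA, rep(NA, nrow(sm) - 3))
  expect_error(suppressMessages(rin_time_regression(sm)), ">= 3")
})

test_that("null RIN p-values are uniform over replicates", {
  sm <- design_table()
  set.seed(314)
  ps <- replicate(200, {
    sm$rin <- rnorm(nrow(sm), 7, 0.5)
    rin_time_regression(sm)$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Poisson count model recovers a two-group log difference", {
  sm <- design_table()
  counts <- round(exp(9 + 0.0366 * (sm$tumor_type == "LC")))
  tab <- detection_count_model(setNames(counts, sm$sample_id), sm,
                               array_effects = "none")
  est <- tab$estimate[grepl("tumor_type", tab$term)]
  expect_equal(est, 0.0366, tolerance = 1e-3) # counts are rounded to integers
  expect_equal(tab$pct_diff[grepl("tumor_type", tab$term)], 3.7,
               tolerance = 0.05)
  # equal counts everywhere -> all non-intercept coefficients ~ 0
  tab0 <- detection_count_model(setNames(rep(9000L, nrow(sm)), sm$sample_id),
                                sm, array_effects = "none")
  expect_true(all(abs(tab0$estimate[tab0$term != "(Intercept)"]) < 1e-8))
  expect_error(detection_count_model(counts + 0.5, sm), "integers")
})

test_that("Poisson model time p-values are uniform under the null", {
  sm <- design_table()
  set.seed(271)
  ps <- replicate(150, {
    counts <- rpois(nrow(sm), 9000)
    tab <- detection_count_model(setNames(counts, sm$sample_id), sm,
                                 array_effects = "none")
    tab$p[tab$term == "t"]
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("central/peripheral r2 matches hand-computed Pearson values", {
  es <- tiny_expr_set(3, times = 5)
  es$signal <- matrix(exp(c(1, 2, 3, 1, 3, 2)), 3, 2,
                      dimnames = dimnames(es$signal))
  r2 <- central_peripheral_r2(es)
  expect_equal(r2$r2, 0.25, tolerance = 1e-12) # r = 0.5 by hand
  # identical columns -> r2 = 1
  es$signal[, 2] <- es$signal[, 1]
  expect_equal(central_peripheral_r2(es)$r2, 1, tolerance = 1e-12)
  # missing site -> stratum skipped with warning
  es2 <- tiny_expr_set(3, times = 5)
  es2 <- subset_samples_for_test(es2, es2$samples$site == "central")
  expect_warning(r <- central_peripheral_r2(es2), "skipped")
  expect_null(r)
})

test_that("qc_report assembles one row per sample with pass flags", {
  sim <- simulate_dataset(small_config(n_probes = 1200, seed = 17L))
  qc <- suppressMessages(qc_report(sim$data, array_effects = "fixed"))
  expect_equal(nrow(qc$samples), 48)
  expect_true(all(qc$samples$pass_p95p05 == (qc$samples$p95_p05 > 10)))
  expect_true(all(qc$samples$detected_genes <=
                    length(unique(sim$data$probes$symbol))))
  expect_true(all(c("t") %in% qc$detection_count_model$term))
  expect_equal(nrow(qc$central_peripheral_r2), 24)
})
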
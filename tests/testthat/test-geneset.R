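test_that("gene-level pooling is inverse-variance weighted on the slope", {
  one <- pool_gene_rate(0.2, 0.01)
  expect_equal(one$beta, 0.2)
  expect_equal(one$rate_pct_per_hr, rate_pct_per_hr(0.2))
  eq <- pool_gene_rate(c(0.1, 0.3), c(0.01, 0.01))
  expect_equal(eq$beta, 0.2)
  # hand computation: (100*0.1 + 11.111*0.4) / 111.111
  two <- pool_gene_rate(c(0.1, 0.4), c(0.01, 0.09))
  expect_equal(two$beta, (100 * 0.1 + (1 / 0.09) * 0.4) / (100 + 1 / 0.09),
               tolerance = 1e-12)
  expect_equal(round(two$beta, 3), 0.13)
  expect_equal(two$se, sqrt(1 / (100 + 1 / 0.09)), tolerance = 1e-12)
  # invariant to probe ordering
  expect_equal(pool_gene_rate(c(0.4, 0.1), c(0.09, 0.01))$beta, two$beta)
})

test_that("Neyman components follow the closed-form Legendre scores", {
  # symmetric set ranks -> linear component exactly 0
  stats <- setNames(1:100, sprintf("i%03d", 1:100))
  sym_set <- names(stats)[c(10, 91, 25, 76, 40, 61)] # u pairs summing to 1
  res <- neyman_rank_test(stats, sym_set)
  expect_equal(res$beta_linear, 0, tolerance = 1e-12)
  # SE structure: 1/sqrt(m), e.g. m = 31 -> 0.1796
  res31 <- neyman_rank_test(setNames(1:1000, paste0("i", 1:1000)),
                            paste0("i", seq(10, 310, by = 10)))
  expect_equal(res31$m, 31)
  expect_equal(res31$se_linear, 1 / sqrt(31))
  expect_equal(round(res31$se_linear, 2), 0.18)
  # set wholly inside the top 1% of N = 10000
  N <- 10000
  stats <- setNames(seq_len(N), sprintf("g%05d", seq_len(N)))
  top <- names(stats)[(N - 29):N]
  res_top <- neyman_rank_test(stats, top)
  expect_gt(res_top$beta_linear, sqrt(3) * (2 * 0.99 - 1))
  expect_lt(res_top$p_linear, 1e-10)
  expect_error(neyman_rank_test(stats, c(top, "missing1")), "missing1")
  expect_error(neyman_rank_test(stats, names(stats)[1:3]), ">= 5")
})

test_that("reversing all ranks flips the linear component and fixes the
           quadratic", {
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(500)
    names(x) <- sprintf("p%03d", 1:500)
    set <- sample(names(x), 25)
    a <- neyman_rank_test(x, set)
    b <- neyman_rank_test(-x, set)
    expect_equal(b$beta_linear, -a$beta_linear, tolerance = 1e-12)
    expect_equal(b$beta_quad, a$beta_quad, tolerance = 1e-12)
  }
})

test_that("null Neyman variance scales as 1/m", {
  set.seed(18)
  m <- 30
  N <- 10000
  b1 <- replicate(1000, {
    sel <- logical(N)
    sel[sample.int(N, m)] <- TRUE
    u <- (seq_len(N) - 0.5) / N
    mean(sqrt(3) * (2 * u[sel] - 1))
  })
  expect_lt(abs(var(b1) * m - 1), 0.1)
})

test_that("geneset_neyman maps symbols to probes and offers both variants", {
  fits <- data.frame(probe_id = sprintf("p%03d", 1:200),
                     beta_linear = c(rep(2, 6), rnorm(194)),
                     se_linear = rep(1, 200), stringsAsFactors = FALSE)
  ann <- data.frame(probe_id = fits$probe_id,
                    symbol = c(rep("SIG", 6), sprintf("G%03d", 7:200)),
                    stringsAsFactors = FALSE)
  res <- geneset_neyman(fits, ann, "SIG", variants = c("raw", "se_normalized"))
  expect_named(res, c("raw", "se_normalized"))
  expect_gt(res$raw$beta_linear, 1) # all six probes at the top
  expect_equal(res$raw$m, 6)
  expect_error(geneset_neyman(fits, ann, c("SIG", "ABSENT")), "ABSENT")
  expect_warning(
    geneset_neyman(fits, ann, c("SIG", "ABSENT"), require_all = FALSE),
    "ABSENT")
})

test_that("direction consistency recovers a logistic slope within clustered
           uncertainty", {
  set.seed(42)
  ok <- 0
  for (rep in 1:20) {
    n_genes <- 200
    rate <- rnorm(n_genes, 0, 1.5)
    slope_true <- 0.8
    genes <- sprintf("G%03d", seq_len(n_genes))
    n_rep <- sample(2:5, n_genes, replace = TRUE)
    calls <- data.frame(
      gene_symbol = rep(genes, n_rep),
      study_id = paste0("s", seq_len(sum(n_rep))),
      direction = ifelse(
        rbinom(sum(n_rep), 1, 1 / (1 + exp(-slope_true * rep(rate, n_rep)))),
        "up", "down"),
      stringsAsFactors = FALSE
    )
    pooled <- data.frame(symbol = genes, rate_pct_per_hr = rate,
                         stringsAsFactors = FALSE)
    res <- suppressWarnings(direction_consistency(pooled, calls))
    if (abs(res$slope - slope_true) <= 2 * res$se) ok <- ok + 1
  }
  expect_gte(ok / 20, 0.9)
})

test_that("complete separation triggers the penalized fallback with a flag", {
  genes <- sprintf("G%02d", 1:12)
  pooled <- data.frame(symbol = genes,
                       rate_pct_per_hr = c(1:6, -(1:6)),
                       stringsAsFactors = FALSE)
  calls <- data.frame(gene_symbol = genes, study_id = paste0("s", 1:12),
                      direction = c(rep("up", 6), rep("down", 6)),
                      stringsAsFactors = FALSE)
  expect_warning(res <- direction_consistency(pooled, calls), "separation")
  expect_true(res$penalized)
  expect_true(is.finite(res$slope) && is.finite(res$se))
})

test_that("per-gene consistency calls follow the majority direction", {
  pooled <- data.frame(symbol = c("GPC3", "MTX", "TIED"),
                       rate_pct_per_hr = c(0.36, -0.4, 1),
                       stringsAsFactors = FALSE)
  calls <- data.frame(
    gene_symbol = c(rep("GPC3", 4), rep("MTX", 3), rep("TIED", 2)),
    study_id = paste0("s", 1:9),
    direction = c("up", "up", "up", "down", "down", "down", "up",
                  "up", "down"),
    stringsAsFactors = FALSE
  )
  res <- suppressWarnings(direction_consistency(pooled, calls))
  g <- res$genes
  # 3 up vs 1 down with positive rate: consistent
  expect_true(g$consistent[g$symbol == "GPC3"])
  expect_equal(g$n_up_reports[g$symbol == "GPC3"], 3)
  # majority down with negative rate: consistent
  expect_true(g$consistent[g$symbol == "MTX"])
  # tie: majority undefined
  expect_true(is.na(g$consistent[g$symbol == "TIED"]))
})

test_that("packaged fixtures drive a full consistency analysis", {
  calls <- read_literature_calls(
    system.file("extdata", "liverome_hcc_calls.csv", package = "warmclock"))
  set.seed(6)
  pooled <- data.frame(symbol = unique(calls$gene_symbol),
                       rate_pct_per_hr = rnorm(34, 0, 0.5),
                       stringsAsFactors = FALSE)
  res <- suppressWarnings(suppressMessages(
    direction_consistency(pooled, calls)))
  expect_equal(res$n_genes, 34)
  expect_equal(res$n_reports, nrow(calls))
  expect_true(all(!is.na(res$genes$consistent) |
                    res$genes$n_up_reports == res$genes$n_down_reports))
})
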
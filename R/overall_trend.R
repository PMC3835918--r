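#' Per-sample inverse-variance weighted mean log expression
#'
#' Combines all probes of a sample into a minimum-variance estimate of mean
#' log expression (the log geometric mean), weighting each probe by the
#' reciprocal of its variance; the returned variance is `1 / sum(w)`.
#'
#' @param log_expr probes x samples log-expression matrix.
#' @param probe_variances positive per-probe variance estimates (typically
#'   from [probe_variances()]).
#' @return data.frame with `sample_id`, `mean_log`, `variance`.
#' @export
weighted_mean_log <- function(log_expr, probe_variances) {
  stopifnot(length(probe_variances) == nrow(log_expr))
  if (any(!is.finite(probe_variances)) || any(probe_variances <= 0)) {
    stop("probe variances must be positive and finite")
  }
  w <- 1 / probe_variances
  data.frame(
    sample_id = colnames(log_expr),
    mean_log = colSums(log_expr * w) / sum(w),
    variance = 1 / sum(w),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Per-probe residual variance around the quadratic time trend
#'
#' Residual variance of each probe around its own per-series quadratic time
#' model (series intercepts + linear + quadratic time), the same model the
#' per-probe tests use. These are the weights' source for
#' [weighted_mean_log()].
#'
#' @param log_expr probes x samples log-expression matrix.
#' @param samples matching sample design table.
#' @param pool_sites treat central/peripheral as technical replicates of one
#'   series (see [sample_series()]).
#' @param floor lower bound applied to the variances so constant probes do
#'   not produce infinite weights.
#' @return named numeric vector of variances.
#' @export
probe_variances <- function(log_expr, samples, pool_sites = FALSE,
                            floor = 1e-8) {
  des <- timecourse_design(samples, pool_sites = pool_sites)
  R1 <- log_expr %*% des$M1 # residual maker of the full model
  rss <- rowSums(R1^2)
  pmax(rss / des$df2, floor)
}

#' Genome-wide expression trend (percent per hour)
#'
#' Fits a random-intercept linear mixed model of per-sample mean log
#' expression on delay to cryopreservation (hours), with one intercept per
#' tissue series (patient x tumor type x site), and reports the slope as a
#' multiplicative percent-per-hour rate, `100 * (exp(beta) - 1)`, with a
#' Wald 95% CI transformed the same way. A second fit adds a quadratic term
#' in centered time and reports its Wald p-value. Estimation is by REML;
#' with a single series (or a degenerate fit) the model falls back to
#' ordinary least squares with a warning.
#'
#' @param summaries output of [weighted_mean_log()].
#' @param samples matching sample design table (>= 3 distinct times).
#' @param label subset label carried into the result row.
#' @param n_probes number of probes behind the summaries (reported only).
#' @param pool_sites see [sample_series()].
#' @param rate_scale see [rate_pct_per_hr()].
#' @return one-row data.frame: label, rate_pct_per_hr, ci95_low, ci95_high,
#'   p_linear, p_quadratic, n_samples, n_probes.
#' @export
fit_overall_trend <- function(summaries, samples, label = "all",
                              n_probes = NA_integer_, pool_sites = FALSE,
                              rate_scale = c("multiplicative", "linear")) {
  rate_scale <- match.arg(rate_scale)
  d <- merge(summaries, samples, by = "sample_id", sort = FALSE)
  if (length(unique(d$time_min)) < 3) {
    stop("need >= 3 distinct time points, got ", length(unique(d$time_min)))
  }
  d$t <- hours(d$time_min)
  d$tc <- d$t - mean(d$t)
  d$series <- sample_series(d, pool_sites = pool_sites)
  one_series <- length(unique(d$series)) < 2

  fit_lin <- function() {
    if (one_series) stop("single series")
    m <- lmerTest::lmer(mean_log ~ t + (1 | series), data = d, REML = TRUE)
    cf <- summary(m)$coefficients
    list(beta = cf["t", "Estimate"], se = cf["t", "Std. Error"],
         df = cf["t", "df"])
  }
  fit_lin_ols <- function() {
    f <- if (one_series) mean_log ~ t else mean_log ~ t + factor(series)
    m <- lm(f, data = d)
    cf <- summary(m)$coefficients
    list(beta = cf["t", "Estimate"], se = cf["t", "Std. Error"],
         df = m$df.residual)
  }
  lin <- tryCatch(suppressMessages(suppressWarnings(fit_lin())),
                  error = function(e) {
                    warning("mixed-model fit unavailable (",
                            conditionMessage(e), "); using OLS")
                    fit_lin_ols()
                  })

  fit_quad <- function() {
    if (one_series) stop("single series")
    m <- lmerTest::lmer(mean_log ~ tc + I(tc^2) + (1 | series), data = d,
                        REML = TRUE)
    cf <- summary(m)$coefficients
    cf["I(tc^2)", c("Estimate", "Std. Error")]
  }
  fit_quad_ols <- function() {
    f <- if (one_series) mean_log ~ tc + I(tc^2)
         else mean_log ~ tc + I(tc^2) + factor(series)
    cf <- summary(lm(f, data = d))$coefficients
    cf["I(tc^2)", c("Estimate", "Std. Error")]
  }
  qd <- tryCatch(suppressMessages(suppressWarnings(fit_quad())),
                 error = function(e) fit_quad_ols())

  # Wald t inference with Satterthwaite df from the mixed model (residual
  # df for the OLS fallback); falls back to a normal quantile if df is
  # unusable
  df_lin <- lin$df
  if (!is.finite(df_lin) || df_lin <= 0) df_lin <- Inf
  tstat <- lin$beta / lin$se
  p_lin <- 2 * stats::pt(-abs(tstat), df_lin)
  if (!is.finite(p_lin)) p_lin <- 1
  zq <- qd[1] / qd[2]
  p_quad <- if (is.finite(zq)) 2 * pnorm(-abs(zq)) else 1
  crit <- stats::qt(0.975, df_lin)
  lo <- lin$beta - crit * lin$se
  hi <- lin$beta + crit * lin$se
  data.frame(
    label = label,
    rate_pct_per_hr = rate_pct_per_hr(lin$beta, rate_scale),
    ci95_low = rate_pct_per_hr(lo, rate_scale),
    ci95_high = rate_pct_per_hr(hi, rate_scale),
    p_linear = p_lin,
    p_quadratic = p_quad,
    n_samples = nrow(d),
    n_probes = n_probes,
    stringsAsFactors = FALSE
  )
}

#' Probes in an expression-level tail
#'
#' Ranks probes by geometric-mean expression across all samples (equivalent
#' to the mean of log values) and returns the requested tail; ties break
#' deterministically by probe id (lexicographically first ids win).
#'
#' @param log_expr probes x samples log-expression matrix with probe-id
#'   rownames.
#' @param fraction tail size as a fraction of probes, in (0, 0.5];
#'   `ceiling(fraction * n)` probes are returned.
#' @param tail `"high"` or `"low"`.
#' @return character vector of probe ids.
#' @export
restrict_by_expression <- function(log_expr, fraction, tail = c("high", "low")) {
  tail <- match.arg(tail)
  if (!nrow(log_expr)) stop("empty matrix")
  if (fraction <= 0 || fraction > 0.5) stop("fraction must be in (0, 0.5]")
  gm <- rowMeans(log_expr)
  ids <- rownames(log_expr)
  k <- ceiling(fraction * nrow(log_expr))
  ord <- if (tail == "high") order(-gm, ids) else order(gm, ids)
  ids[ord[seq_len(k)]]
}

#' Overall-trend table across standard subsets
#'
#' Convenience wrapper reproducing the standard subset layout: all samples,
#' each tumor type, each site, the lowest/highest 5% expression tails, and
#' any supplied gene sets. Each row is a [fit_overall_trend()] result.
#'
#' @param log_expr probes x samples log-expression matrix (log scale, not
#'   quantile-normalized: quantile normalization would remove exactly the
#'   genome-wide trend this estimates).
#' @param samples matching sample design table.
#' @param symbols per-probe gene symbols (needed if `gene_sets` given).
#' @param gene_sets named list of character vectors of gene symbols.
#' @param tail_fraction expression-tail size.
#' @param pool_sites see [sample_series()].
#' @return data.frame, one row per subset.
#' @export
overall_trend_table <- function(log_expr, samples, symbols = NULL,
                                gene_sets = NULL, tail_fraction = 0.05,
                                pool_sites = FALSE) {
  run <- function(mat, sm, label) {
    pv <- probe_variances(mat, sm, pool_sites = pool_sites)
    fit_overall_trend(weighted_mean_log(mat, pv), sm, label = label,
                      n_probes = nrow(mat), pool_sites = pool_sites)
  }
  rows <- list(run(log_expr, samples, "all"))
  for (tt in unique(samples$tumor_type)) {
    sel <- samples$tumor_type == tt
    rows <- c(rows, list(run(log_expr[, sel, drop = FALSE],
                             samples[sel, , drop = FALSE], tt)))
  }
  for (st in unique(samples$site)) {
    sel <- samples$site == st
    rows <- c(rows, list(run(log_expr[, sel, drop = FALSE],
                             samples[sel, , drop = FALSE], st)))
  }
  for (tl in c("low", "high")) {
    ids <- restrict_by_expression(log_expr, tail_fraction, tail = tl)
    rows <- c(rows, list(run(log_expr[ids, , drop = FALSE], samples,
                             paste0(tl, round(100 * tail_fraction)))))
  }
  if (!is.null(gene_sets)) {
    stopifnot(!is.null(symbols), length(symbols) == nrow(log_expr))
    for (nm in names(gene_sets)) {
      sel <- symbols %in% gene_sets[[nm]]
      if (sum(sel) < 2) {
        warning("gene set ", nm, " matches < 2 probes; skipped")
        next
      }
      rows <- c(rows, list(run(log_expr[sel, , drop = FALSE], samples, nm)))
    }
  }
  do.call(rbind, rows)
}
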
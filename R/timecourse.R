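#' Per-probe time-course design matrices
#'
#' Builds the fixed-effect design shared by every probe fit: one intercept
#' per tissue series plus linear and quadratic terms in centered time
#' (hours). Centering decorrelates the two time terms and conditions the
#' fit. Returns residual-maker matrices for the full and the
#' intercepts-only model, the coefficient projector, and degrees of freedom.
#'
#' @param samples sample design table.
#' @param pool_sites see [sample_series()].
#' @return list with `M0`, `M1` (n x n residual makers), `C` (coefficient
#'   projector, n x p), `lin_col`, `quad_col`, `d_lin`, `d_quad` (diagonal
#'   entries of the coefficient covariance factor), `df2`.
#' @keywords internal
timecourse_design <- function(samples, pool_sites = FALSE) {
  t_hr <- hours(samples$time_min)
  tc <- t_hr - mean(t_hr)
  series <- factor(sample_series(samples, pool_sites = pool_sites))
  X0 <- model.matrix(~ 0 + series)
  X1 <- cbind(X0, tc = tc, tc2 = tc^2)
  n <- nrow(X1)
  qr1 <- qr(X1)
  if (qr1$rank < ncol(X1)) {
    stop("rank-deficient time-course design (", qr1$rank, " < ", ncol(X1),
         "); need >= 3 distinct times per series")
  }
  xtx_inv <- chol2inv(chol(crossprod(X1)))
  H1 <- X1 %*% xtx_inv %*% t(X1)
  H0 <- X0 %*% chol2inv(chol(crossprod(X0))) %*% t(X0)
  I_n <- diag(n)
  list(
    M0 = I_n - H0,
    M1 = I_n - H1,
    C = X1 %*% xtx_inv,
    lin_col = ncol(X0) + 1L,
    quad_col = ncol(X0) + 2L,
    d_lin = xtx_inv[ncol(X0) + 1L, ncol(X0) + 1L],
    d_quad = xtx_inv[ncol(X0) + 2L, ncol(X0) + 2L],
    df2 = n - ncol(X1)
  )
}

#' Quadratic time-course fit for every probe
#'
#' For each probe, fits log expression on centered time + time-squared with
#' fixed series intercepts and tests the joint null that both time
#' coefficients are zero with a 2-df F-test against the intercepts-only
#' model: `F = ((RSS0 - RSS1)/2) / (RSS1/df2)`. All probes share one design,
#' so the fit is a closed-form matrix product; the result is invariant to
#' sample column order. Constant probes report F = 0, p = 1.
#'
#' @param log_expr probes x samples log-expression matrix (probe-id
#'   rownames).
#' @param samples matching sample design table (>= 8 samples).
#' @param pool_sites see [sample_series()].
#' @return data.frame, one row per probe: probe_id, beta_linear, se_linear,
#'   beta_quad, se_quad, rate_pct_per_hr, f_stat, p, df2.
#' @export
fit_timecourse <- function(log_expr, samples, pool_sites = FALSE) {
  stopifnot(ncol(log_expr) == nrow(samples))
  if (ncol(log_expr) < 8) stop("need >= 8 samples, got ", ncol(log_expr))
  des <- timecourse_design(samples, pool_sites = pool_sites)
  Y <- log_expr
  rss1 <- rowSums((Y %*% des$M1)^2)
  rss0 <- rowSums((Y %*% des$M0)^2)
  B <- Y %*% des$C
  beta_lin <- B[, des$lin_col]
  beta_quad <- B[, des$quad_col]
  sigma2 <- rss1 / des$df2
  se_lin <- sqrt(sigma2 * des$d_lin)
  se_quad <- sqrt(sigma2 * des$d_quad)

  scale0 <- pmax(rowSums(Y^2), 1)
  is_const <- rss0 <= 1e-20 * scale0
  num <- pmax(rss0 - rss1, 0) / 2
  den <- sigma2
  f_stat <- ifelse(is_const, 0,
                   ifelse(den <= 1e-20 * scale0, Inf, num / den))
  p <- ifelse(is_const, 1, pf(f_stat, 2, des$df2, lower.tail = FALSE))
  data.frame(
    probe_id = rownames(Y) %||% sprintf("probe%d", seq_len(nrow(Y))),
    beta_linear = unname(beta_lin),
    se_linear = unname(se_lin),
    beta_quad = unname(beta_quad),
    se_quad = unname(se_quad),
    rate_pct_per_hr = rate_pct_per_hr(unname(beta_lin)),
    f_stat = unname(f_stat),
    p = unname(p),
    df2 = des$df2,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Time-course fit for a single probe
#' @param y log-expression vector of one probe (one value per sample).
#' @inheritParams fit_timecourse
#' @return one-row data.frame as in [fit_timecourse()].
#' @export
fit_probe <- function(y, samples, pool_sites = FALSE) {
  fit_timecourse(matrix(y, nrow = 1, dimnames = list("probe1", NULL)),
                 samples, pool_sites = pool_sites)
}

#' False-discovery-rate adjustment
#'
#' Benjamini-Hochberg step-up q-values (optionally Benjamini-Yekutieli);
#' q >= p always, and q is monotone in the p-value ranks.
#'
#' @param p p-values in \[0, 1\]; NA/NaN is an error.
#' @param method `"BH"` (default) or `"BY"`.
#' @return q-values, same length as `p`.
#' @export
fdr_adjust <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(is.na(p))) stop("p-values contain NA/NaN")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}

#' Annotate probe fits with q-values and directions
#'
#' Adds BH q-values and a direction call: `up`/`down` from the sign of the
#' linear coefficient when q is below `threshold`, `none` otherwise. Probes
#' whose significance is driven by the quadratic term alone (linear Wald
#' |z| < 1.96) are flagged `nonmonotone`.
#'
#' @param fits output of [fit_timecourse()].
#' @param threshold FDR threshold.
#' @inheritParams fdr_adjust
#' @return `fits` with columns q, direction, nonmonotone added.
#' @export
fdr_annotate <- function(fits, threshold = 0.05, method = c("BH", "BY")) {
  fits$q <- fdr_adjust(fits$p, method = match.arg(method))
  z_lin <- ifelse(fits$se_linear > 0, fits$beta_linear / fits$se_linear,
                  ifelse(fits$beta_linear == 0, 0, Inf))
  fits$direction <- ifelse(fits$q < threshold,
                           ifelse(fits$beta_linear > 0, "up", "down"),
                           "none")
  fits$nonmonotone <- fits$direction != "none" & abs(z_lin) < 1.959964
  fits
}

#' Gene-level table of significant time-course changes
#'
#' A gene is flagged when any of its probes has q below `threshold`; its
#' direction comes from the most significant probe's linear coefficient.
#' Tumor types are analyzed independently upstream, so `fits` should come
#' from one tumor type's samples.
#'
#' @param fits output of [fit_timecourse()].
#' @param annotation data.frame with `probe_id`, `symbol`.
#' @param threshold FDR threshold.
#' @inheritParams fdr_adjust
#' @return data.frame (possibly 0 rows): symbol, probe_id (most significant
#'   probe), q, p, beta_linear, rate_pct_per_hr, direction, nonmonotone.
#' @export
significant_genes <- function(fits, annotation, threshold = 0.05,
                              method = c("BH", "BY")) {
  ann <- fdr_annotate(fits, threshold = threshold, method = method)
  ann <- merge(ann, annotation[, c("probe_id", "symbol")], by = "probe_id")
  sig <- ann[ann$q < threshold, , drop = FALSE]
  cols <- c("symbol", "probe_id", "q", "p", "beta_linear",
            "rate_pct_per_hr", "direction", "nonmonotone")
  if (!nrow(sig)) {
    return(sig[, cols])
  }
  sig <- sig[order(sig$q, sig$p, sig$probe_id), , drop = FALSE]
  best <- sig[!duplicated(sig$symbol), , drop = FALSE]
  best <- best[order(best$q, best$p, best$symbol), cols]
  rownames(best) <- NULL
  best
}
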
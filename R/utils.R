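#' Convert a log-scale slope per hour to a percent-per-hour rate
#'
#' Expression decay is modelled multiplicatively on the natural-log scale; a
#' slope `beta` (log-units per hour) corresponds to a relative change of
#' `exp(beta) - 1` per hour. `rate_pct_per_hr(0)` is exactly 0 and the map is
#' strictly increasing.
#'
#' @param beta log-scale slope per hour (natural log).
#' @param scale `"multiplicative"` (default) returns `100 * (exp(beta) - 1)`;
#'   `"linear"` returns `100 * beta`, offered for comparability with analyses
#'   that read the slope directly as a percentage.
#' @return numeric rate in percent per hour.
#' @export
rate_pct_per_hr <- function(beta, scale = c("multiplicative", "linear")) {
  scale <- match.arg(scale)
  if (scale == "multiplicative") 100 * (expm1(beta)) else 100 * beta
}

#' Inverse of [rate_pct_per_hr()]
#' @param rate percent per hour.
#' @inheritParams rate_pct_per_hr
#' @return log-scale slope per hour.
#' @export
slope_from_rate <- function(rate, scale = c("multiplicative", "linear")) {
  scale <- match.arg(scale)
  if (scale == "multiplicative") log1p(rate / 100) else rate / 100
}

# minutes -> hours; the design stores time in minutes, all models use hours
hours <- function(time_min) time_min / 60

# deterministic per-component sub-seed from one master seed (kept < 2^31)
component_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

# truncated-normal draw (lower bound only), via inverse-CDF so it is cheap
# and deterministic under set.seed()
rtruncnorm_lower <- function(n, mean, sd, lower) {
  plo <- pnorm(lower, mean, sd)
  qnorm(runif(n, plo, 1), mean, sd)
}

#' Inverse-variance weighted mean
#'
#' Minimum-variance combination of independent estimates: weights are
#' reciprocal variances, the combined variance is `1 / sum(w)`.
#'
#' @param x estimates.
#' @param variances positive variances, same length as `x`.
#' @return list with `mean` and `variance`.
#' @export
inverse_variance_mean <- function(x, variances) {
  stopifnot(length(x) == length(variances))
  if (any(!is.finite(variances)) || any(variances <= 0)) {
    stop("all variances must be positive and finite")
  }
  w <- 1 / variances
  list(mean = sum(w * x) / sum(w), variance = 1 / sum(w))
}

# Firth-penalized logistic regression (Newton iterations on the modified
# score U* = X'(y - p + h (0.5 - p))).  Used only as a fallback when the
# block-logistic consistency model separates completely.
firth_logistic <- function(X, y, max_iter = 50, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    XtW <- t(X * W)
    info <- XtW %*% X
    info_inv <- solve(info)
    h <- rowSums((X %*% info_inv) * (X * W))
    score <- drop(t(X) %*% (y - p + h * (0.5 - p)))
    step <- drop(info_inv %*% score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  info <- t(X * (p * (1 - p))) %*% X
  list(coefficients = beta, vcov = solve(info))
}
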
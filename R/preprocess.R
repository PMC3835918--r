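#' Natural-log transform with a signal floor
#'
#' Bead-set noise scales with mean signal, so raw signals are log-transformed
#' before any modelling; the log scale is where the data are homoskedastic.
#' Signals below `floor` (default 1 on the raw scale) are floored first so
#' the log is always defined; the number of floored entries is logged.
#'
#' @param signal non-negative raw signal matrix (probes x samples).
#' @param floor raw-scale floor applied before the log.
#' @return matrix of natural-log signals.
#' @export
log_transform <- function(signal, floor = 1) {
  n_floored <- sum(signal < floor)
  if (n_floored > 0) {
    message("floored ", n_floored, " signal value(s) below ", floor)
  }
  log(pmax(signal, floor))
}

#' Quantile normalization
#'
#' Forces every sample's empirical distribution onto the across-sample mean
#' quantile function, preserving within-sample ranks; tied values receive
#' the mean of their tied quantiles. Idempotent, and afterwards every
#' sample's sorted value vector is identical.
#'
#' @param log_expr matrix (probes x samples, >= 2 samples), log scale.
#' @return quantile-normalized matrix of the same shape.
#' @export
quantile_normalize <- function(log_expr) {
  if (ncol(log_expr) < 2) stop("quantile normalization needs >= 2 samples")
  out <- limma::normalizeQuantiles(log_expr, ties = TRUE)
  dimnames(out) <- dimnames(log_expr)
  out
}

#' Excess-dispersion probe filter
#'
#' A probe is excluded when strictly more than `frac` (default 80%) of its
#' raw-scale values differ from the probe median by more than `fold`
#' (default 1.5-fold), i.e. `max(v/m, m/v) > fold`. Fold change is a
#' linear-scale notion, so the rule is evaluated on raw signals.
#'
#' @param signal raw-scale signal matrix (probes x samples).
#' @param fold fold-change cutoff.
#' @param frac fraction of discordant values beyond which a probe is
#'   excluded.
#' @return logical vector, TRUE = excluded, named by probe id.
#' @export
dispersion_filter <- function(signal, fold = 1.5, frac = 0.8) {
  med <- matrixStats::rowMedians(signal)
  ratio <- pmax(signal / med, med / signal)
  discordant <- rowMeans(ratio > fold)
  setNames(discordant > frac, rownames(signal))
}

#' Detection-based probe eligibility
#'
#' A probe is eligible for time-course testing when it is detected
#' (detection p-value below `p_threshold`) in at least `min_frac` of samples
#' and is not excluded by the excess-dispersion rule. Every probe gets
#' exactly one status: `kept`, `excluded_undetected` (checked first) or
#' `excluded_dispersion`.
#'
#' @param signal raw-scale signal matrix.
#' @param det_pvals matching detection p-value matrix.
#' @param min_frac minimum fraction of samples in which a probe must be
#'   detected.
#' @param p_threshold detection p-value cutoff.
#' @inheritParams dispersion_filter
#' @return list with `eligible` (logical vector) and `filter_log`
#'   (data.frame probe_id, status).
#' @export
eligibility_filter <- function(signal, det_pvals, min_frac = 0.5,
                               p_threshold = 0.01, fold = 1.5, frac = 0.8) {
  stopifnot(all(dim(signal) == dim(det_pvals)))
  detected_enough <- rowMeans(det_pvals < p_threshold) >= min_frac
  dispersed <- dispersion_filter(signal, fold = fold, frac = frac)
  status <- ifelse(!detected_enough, "excluded_undetected",
                   ifelse(dispersed, "excluded_dispersion", "kept"))
  eligible <- status == "kept"
  message(sum(eligible), " of ", nrow(signal), " probes eligible (",
          round(100 * mean(eligible), 1), "%)")
  list(
    eligible = setNames(eligible, rownames(signal)),
    filter_log = data.frame(probe_id = rownames(signal), status = status,
                            stringsAsFactors = FALSE)
  )
}

#' Eligible-probe percentage
#'
#' Percentage of probes passing the filtering criteria, rounded to one
#' decimal, as reported alongside filtered probe counts.
#'
#' @param n_eligible,n_total probe counts.
#' @return percentage, one decimal.
#' @export
eligible_fraction_pct <- function(n_eligible, n_total) {
  round(100 * n_eligible / n_total, 1)
}

#' Log-transform, filter and quantile-normalize an expression set
#'
#' The analysis-ready matrix: probes are filtered (detection eligibility +
#' excess dispersion, both on the raw scale), then the kept probes are
#' log-transformed and quantile-normalized.
#'
#' @param es an [expr_set()].
#' @param det_pvals detection p-values (computed via [detection_pvalues()]
#'   if omitted).
#' @inheritParams eligibility_filter
#' @inheritParams log_transform
#' @return list of class `norm_set`: `log_expr` (kept probes x samples,
#'   natural-log, quantile-normalized), `samples`, `probes` (kept
#'   annotation), `filter_log`.
#' @export
normalize_matrix <- function(es, det_pvals = NULL, min_frac = 0.5,
                             p_threshold = 0.01, fold = 1.5, frac = 0.8,
                             floor = 1) {
  if (is.null(det_pvals)) det_pvals <- detection_pvalues(es)
  flt <- eligibility_filter(es$signal, det_pvals, min_frac = min_frac,
                            p_threshold = p_threshold, fold = fold,
                            frac = frac)
  keep <- flt$eligible
  log_expr <- quantile_normalize(log_transform(es$signal[keep, , drop = FALSE],
                                               floor = floor))
  structure(
    list(log_expr = log_expr,
         samples = es$samples,
         probes = es$probes[keep, , drop = FALSE],
         filter_log = flt$filter_log),
    class = "norm_set"
  )
}

#' @export
print.norm_set <- function(x, ...) {
  cat("norm_set:", nrow(x$log_expr), "kept probes x", ncol(x$log_expr),
      "samples (quantile-normalized natural-log scale)\n")
  invisible(x)
}
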
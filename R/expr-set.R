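#' Raw bead-array expression set
#'
#' Container for one experiment: a probes x samples matrix of raw average
#' signals (no normalization, no background subtraction), the matched
#' negative-control probe signals, optional per-probe/sample bead-set
#' standard deviations, probe annotation (1-3 probes per gene) and the sample
#' design table.
#'
#' @param signal numeric matrix, probes x samples, non-negative raw signals;
#'   rownames are probe ids, colnames sample ids.
#' @param negatives numeric matrix, negative-control probes x samples, same
#'   column order as `signal`.
#' @param probes data.frame with columns `probe_id`, `symbol` (one row per
#'   probe, same order as `signal` rows).
#' @param samples data.frame with columns `sample_id`, `patient`,
#'   `tumor_type`, `site`, `time_min`, `rin`, `array_id`, `array_position`
#'   (one row per sample, same order as `signal` columns). `rin` may be NA.
#' @param bead_sd optional numeric matrix, probes x samples, within-array
#'   bead-set standard deviation of each probe's signal.
#' @return object of class `expr_set`.
#' @export
expr_set <- function(signal, negatives, probes, samples, bead_sd = NULL) {
  signal <- as.matrix(signal)
  negatives <- as.matrix(negatives)
  if (any(signal < 0)) stop("signal matrix contains negative values")
  if (any(negatives < 0)) stop("negative-control matrix contains negative values")
  if (nrow(probes) != nrow(signal)) {
    stop("probe annotation rows (", nrow(probes), ") != signal rows (",
         nrow(signal), ")")
  }
  if (nrow(samples) != ncol(signal)) {
    stop("sample table rows (", nrow(samples), ") != signal columns (",
         ncol(signal), ")")
  }
  if (ncol(negatives) != ncol(signal)) {
    stop("negative-control columns != signal columns")
  }
  if (anyDuplicated(probes$probe_id)) {
    stop("duplicate probe ids: ",
         paste(unique(probes$probe_id[duplicated(probes$probe_id)])[1:3],
               collapse = ", "))
  }
  if (any(is.na(probes$symbol)) || any(probes$symbol == "")) {
    stop("every probe needs a gene symbol")
  }
  ok_rin <- is.na(samples$rin) | (samples$rin >= 1 & samples$rin <= 10)
  if (!all(ok_rin)) stop("RIN values must lie in [1, 10] or be NA")
  if (any(samples$time_min <= 0)) stop("time_min must be positive")
  rownames(signal) <- probes$probe_id
  colnames(signal) <- samples$sample_id
  colnames(negatives) <- samples$sample_id
  if (!is.null(bead_sd)) {
    bead_sd <- as.matrix(bead_sd)
    stopifnot(dim(bead_sd) == dim(signal))
    dimnames(bead_sd) <- dimnames(signal)
  }
  structure(
    list(signal = signal, negatives = negatives, bead_sd = bead_sd,
         probes = probes, samples = samples),
    class = "expr_set"
  )
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set:", nrow(x$signal), "probes x", ncol(x$signal), "samples;",
      nrow(x$negatives), "negative controls;",
      length(unique(x$probes$symbol)), "genes\n")
  cat("design:", paste(sort(unique(x$samples$tumor_type)), collapse = "/"),
      "|", length(unique(x$samples$patient)), "patients |",
      "times (min):", paste(sort(unique(x$samples$time_min)), collapse = ","),
      "\n")
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$signal)

#' Series label for each sample
#'
#' A "series" is the finest exchangeable unit of the design: one tissue piece
#' followed over time, i.e. patient x tumor type x site. Samples of one
#' series differ only in delay to cryopreservation.
#'
#' @param samples sample design table (see [expr_set()]).
#' @param pool_sites if TRUE, central and peripheral samples of a tumor are
#'   treated as technical replicates of one series (patient x tumor type).
#' @return character vector of series labels, one per sample row.
#' @export
sample_series <- function(samples, pool_sites = FALSE) {
  if (pool_sites) {
    paste(samples$tumor_type, samples$patient, sep = ".")
  } else {
    paste(samples$tumor_type, samples$patient, samples$site, sep = ".")
  }
}

# subset an expr_set by sample index (internal)
subset_samples <- function(es, idx) {
  expr_set(es$signal[, idx, drop = FALSE],
           es$negatives[, idx, drop = FALSE],
           es$probes,
           es$samples[idx, , drop = FALSE],
           bead_sd = if (!is.null(es$bead_sd)) es$bead_sd[, idx, drop = FALSE])
}
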
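#' Detection p-values against negative controls
#'
#' For each sample, a probe's detection p-value is the add-one empirical
#' exceedance probability of its signal among that sample's negative-control
#' signals: `p = (1 + #{controls >= signal}) / (N + 1)`. A signal below every
#' control gets p = 1; one above all N controls gets `1/(N+1)`. A probe is
#' called detected when p < `threshold` (0.01 by convention), so resolving
#' that threshold needs N >= 100 controls.
#'
#' @param es an [expr_set()] (needs >= 20 negative controls per sample).
#' @return probes x samples matrix of p-values in (0, 1].
#' @export
detection_pvalues <- function(es) {
  N <- nrow(es$negatives)
  if (is.null(N) || N == 0) stop("no negative controls available")
  if (N < 20) stop("need >= 20 negative controls per sample, got ", N)
  p <- matrix(NA_real_, nrow(es$signal), ncol(es$signal),
              dimnames = dimnames(es$signal))
  for (s in seq_len(ncol(es$signal))) {
    sneg <- sort(es$negatives[, s])
    n_lt <- findInterval(es$signal[, s], sneg, left.open = TRUE)
    p[, s] <- (1 + N - n_lt) / (N + 1)
  }
  p
}

#' Per-sample detected-gene counts
#'
#' A gene counts as detected in a sample when any of its probes is detected
#' (p below `threshold`) there; probes of one gene target the same
#' transcript set, so the any-probe rule counts genes, not probes.
#'
#' @param pvals probes x samples detection p-values.
#' @param symbols per-probe gene symbol (same order as `pvals` rows).
#' @param threshold detection p-value cutoff.
#' @return named integer vector, one count per sample.
#' @export
detected_gene_counts <- function(pvals, symbols, threshold = 0.01) {
  stopifnot(length(symbols) == nrow(pvals))
  det <- pvals < threshold
  per_gene <- rowsum(det + 0L, group = symbols)
  counts <- colSums(per_gene > 0L)
  setNames(as.integer(counts), colnames(pvals))
}

#' P95/P05 signal-strength ratio
#'
#' Ratio of the 95th to the 5th percentile of one sample's raw signals
#' (linear-interpolation percentiles); reflects overall signal strength over
#' background. Ratios above 10 pass. Scale-invariant: multiplying a sample
#' by c > 0 leaves the ratio unchanged.
#'
#' @param x raw (non-normalized) signal vector of one sample.
#' @return list with `ratio` and logical `pass`.
#' @export
p95_p05_ratio <- function(x) {
  q <- quantile(x, c(0.05, 0.95), names = FALSE, type = 7)
  if (q[1] <= 0) stop("5th percentile is <= 0; signals must be positive")
  ratio <- q[2] / q[1]
  list(ratio = ratio, pass = ratio > 10)
}

#' Linear regression of RIN on time to cryopreservation
#'
#' Ordinary least squares of RIN on delay (in hours); rows with missing RIN
#' are dropped with a logged count. A zero-variance response reports slope 0
#' and p = 1.
#'
#' @param samples sample design table with `rin` and `time_min`.
#' @return list with `slope_per_hr`, `se`, `p`, `n_used`, `n_dropped`.
#' @export
rin_time_regression <- function(samples) {
  keep <- !is.na(samples$rin)
  n_dropped <- sum(!keep)
  if (n_dropped) message("dropped ", n_dropped, " sample(s) with missing RIN")
  d <- data.frame(rin = samples$rin[keep], t = hours(samples$time_min[keep]))
  if (nrow(d) < 3) stop("need >= 3 samples with non-missing RIN, got ", nrow(d))
  fit <- lm(rin ~ t, data = d)
  # degenerate inputs (constant RIN, exact fits) trip summary.lm warnings;
  # those cases are handled explicitly below
  cf <- suppressWarnings(summary(fit))$coefficients
  slope <- cf["t", "Estimate"]
  se <- cf["t", "Std. Error"]
  p <- cf["t", "Pr(>|t|)"]
  if (sd(d$rin) == 0 || !is.finite(p)) {
    slope <- 0
    p <- 1
    se <- NA_real_
  }
  list(slope_per_hr = slope, se = se, p = p,
       n_used = nrow(d), n_dropped = n_dropped)
}

#' Poisson regression of detected-gene counts on the design
#'
#' Log-link Poisson model of per-sample detected-gene counts on delay (hours)
#' plus whichever of site, tumor type, RIN and patient vary in the design.
#' Array and array position enter as exchangeable Gaussian random intercepts
#' (Poisson GLMM via lme4); with very few arrays that variance component is
#' weakly identified, so `array_effects = "fixed"` (fixed array term +
#' cluster-robust sandwich SEs) and `"none"` are offered, and the GLMM falls
#' back to the fixed-effect fit if it fails. Coefficients are also reported
#' as percent differences, `100 * (exp(beta) - 1)`.
#'
#' @param counts named integer vector of detected-gene counts per sample.
#' @param samples matching sample design table.
#' @param array_effects how to absorb array/array-position effects.
#' @return data.frame with term, estimate, se, p, pct_diff.
#' @export
detection_count_model <- function(counts, samples,
                                  array_effects = c("random", "fixed", "none")) {
  array_effects <- match.arg(array_effects)
  if (any(counts != round(counts))) stop("counts must be integers")
  d <- samples
  d$count <- if (!is.null(names(counts))) {
    as.integer(counts[d$sample_id])
  } else {
    as.integer(counts)
  }
  d$t <- hours(d$time_min)
  terms <- "t"
  for (v in c("site", "tumor_type", "rin", "patient")) {
    if (v %in% names(d) && length(unique(d[[v]][!is.na(d[[v]])])) > 1 &&
        !anyNA(d[[v]])) {
      terms <- c(terms, v)
    }
  }
  rhs <- paste(terms, collapse = " + ")
  have_arrays <- all(c("array_id", "array_position") %in% names(d)) &&
    length(unique(d$array_id)) > 1
  fit_fixed <- function() {
    f <- if (have_arrays && array_effects == "fixed") {
      stats::as.formula(paste("count ~", rhs, "+ array_id"))
    } else {
      stats::as.formula(paste("count ~", rhs))
    }
    m <- glm(f, family = poisson(), data = d)
    V <- if (have_arrays && array_effects == "fixed") {
      sandwich::vcovCL(m, cluster = d$array_id)
    } else {
      vcov(m)
    }
    est <- coef(m)
    est <- est[!is.na(est)] # aliased terms (nested factors) are dropped
    se <- sqrt(diag(V))[names(est)]
    data.frame(term = names(est), estimate = unname(est), se = unname(se),
               p = unname(2 * pnorm(-abs(est / se))),
               stringsAsFactors = FALSE)
  }
  tab <- NULL
  if (array_effects == "random" && have_arrays) {
    tab <- tryCatch({
      f <- stats::as.formula(paste("count ~", rhs,
                                   "+ (1 | array_id) + (1 | array_position)"))
      m <- suppressMessages(suppressWarnings(
        lme4::glmer(f, family = poisson(), data = d)
      ))
      cf <- summary(m)$coefficients
      data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                 se = cf[, "Std. Error"], p = cf[, "Pr(>|z|)"],
                 row.names = NULL, stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    if (is.null(tab)) message("Poisson GLMM failed; using fixed-effect fit")
  }
  if (is.null(tab)) tab <- fit_fixed()
  tab$pct_diff <- rate_pct_per_hr(tab$estimate)
  tab
}

#' Central vs peripheral log-signal correlation
#'
#' Squared Pearson correlation of log signals between the central and the
#' peripheral sample of each (patient, tumor type, time) stratum. Strata
#' missing a site are skipped with a warning.
#'
#' @param es an [expr_set()].
#' @return data.frame with patient, tumor_type, time_min, r2.
#' @export
central_peripheral_r2 <- function(es) {
  sm <- es$samples
  keys <- unique(sm[, c("patient", "tumor_type", "time_min")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sel <- sm$patient == k$patient & sm$tumor_type == k$tumor_type &
      sm$time_min == k$time_min
    ic <- which(sel & sm$site == "central")
    ip <- which(sel & sm$site == "peripheral")
    if (!length(ic) || !length(ip)) {
      warning("stratum ", k$patient, "/", k$time_min,
              " lacks a site; skipped")
      next
    }
    r <- cor(log(pmax(es$signal[, ic[1]], 1)),
             log(pmax(es$signal[, ip[1]], 1)))
    out[[length(out) + 1L]] <- data.frame(
      patient = k$patient, tumor_type = k$tumor_type,
      time_min = k$time_min, r2 = r^2, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Assemble the per-sample quality-control report
#'
#' One row per sample: detected genes at p < `threshold`, P95/P05 ratio and
#' pass flag, RIN; plus the RIN-on-time regression, the Poisson
#' detected-count model and central/peripheral r-squared as attributes-free
#' list components.
#'
#' @param es an [expr_set()].
#' @param threshold detection p-value cutoff.
#' @inheritParams detection_count_model
#' @return list with `samples` (Table-1-like data.frame), `rin_regression`,
#'   `detection_count_model`, `central_peripheral_r2`, and the detection
#'   p-value matrix as `detection_pvals`.
#' @export
qc_report <- function(es, threshold = 0.01,
                      array_effects = c("random", "fixed", "none")) {
  pv <- detection_pvalues(es)
  counts <- detected_gene_counts(pv, es$probes$symbol, threshold)
  pp <- lapply(seq_len(ncol(es$signal)),
               function(j) p95_p05_ratio(es$signal[, j]))
  tab <- data.frame(
    sample_id = es$samples$sample_id,
    patient = es$samples$patient,
    tumor_type = es$samples$tumor_type,
    site = es$samples$site,
    time_min = es$samples$time_min,
    rin = es$samples$rin,
    detected_genes = as.integer(counts),
    p95_p05 = vapply(pp, `[[`, numeric(1), "ratio"),
    pass_p95p05 = vapply(pp, `[[`, logical(1), "pass"),
    stringsAsFactors = FALSE
  )
  list(
    samples = tab,
    rin_regression = rin_time_regression(es$samples),
    detection_count_model = detection_count_model(counts, es$samples,
                                                  match.arg(array_effects)),
    central_peripheral_r2 = central_peripheral_r2(es),
    detection_pvals = pv
  )
}
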
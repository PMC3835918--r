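#' Pool multi-probe estimates of one gene
#'
#' Probes of the same gene are combined by inverse-variance weighting on the
#' log-slope scale; the pooled SE is `1/sqrt(sum(w))`.
#'
#' @param betas per-probe linear coefficients (log units per hour).
#' @param variances matching positive variances (squared SEs).
#' @return list with `beta`, `se`, `rate_pct_per_hr`.
#' @export
pool_gene_rate <- function(betas, variances) {
  if (!length(betas)) stop("need >= 1 probe fit")
  iv <- inverse_variance_mean(betas, variances)
  list(beta = iv$mean, se = sqrt(iv$variance),
       rate_pct_per_hr = rate_pct_per_hr(iv$mean))
}

#' Gene-level pooled rates for all genes
#'
#' @param fits output of [fit_timecourse()].
#' @param annotation data.frame with `probe_id`, `symbol`.
#' @param var_floor lower bound on per-probe variances (guards exact fits).
#' @return data.frame: symbol, beta, se, rate_pct_per_hr, n_probes.
#' @export
pool_gene_rates <- function(fits, annotation, var_floor = 1e-8) {
  d <- merge(fits, annotation[, c("probe_id", "symbol")], by = "probe_id")
  d$var <- pmax(d$se_linear^2, var_floor)
  out <- lapply(split(d, d$symbol), function(g) {
    pooled <- pool_gene_rate(g$beta_linear, g$var)
    data.frame(symbol = g$symbol[1], beta = pooled$beta, se = pooled$se,
               rate_pct_per_hr = pooled$rate_pct_per_hr,
               n_probes = nrow(g), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Neyman smooth-contrast test on ranks
#'
#' Competitive gene-set test: do the set members' statistics sit at the
#' extremes of the whole distribution? Mid-ranks `r` of the `m` set members
#' among all `N` statistics are mapped to `u = (r - 0.5)/N` and scored with
#' normalized shifted Legendre polynomials, `phi1(u) = sqrt(3)(2u - 1)`
#' (location shift) and `phi2(u) = sqrt(5)(6u^2 - 6u + 1)` (extremity /
#' dispersion). Each component's estimate is the set mean of the scores,
#' with exact null SE `1/sqrt(m)` and a two-sided normal p-value; a joint
#' 2-df chi-square combines both components (the quadratic-adjusted test).
#'
#' @param statistics named numeric vector of per-item statistics (all items,
#'   set members included).
#' @param set logical vector along `statistics`, or character names of the
#'   set members (>= 5 required).
#' @param set_name,variant labels carried into the result.
#' @return list of class `neyman_result`: set_name, variant, beta_linear,
#'   se_linear, p_linear, beta_quad, se_quad, p_quad, p_joint, m, N.
#' @export
neyman_rank_test <- function(statistics, set, set_name = "set",
                             variant = "raw") {
  N <- length(statistics)
  if (is.character(set)) {
    missing <- setdiff(set, names(statistics))
    if (length(missing)) {
      stop("set members absent from statistics: ",
           paste(missing, collapse = ", "))
    }
    sel <- names(statistics) %in% set
  } else {
    stopifnot(is.logical(set), length(set) == N)
    sel <- set
  }
  m <- sum(sel)
  if (m < 5) stop("need >= 5 set members, got ", m)
  r <- rank(statistics, ties.method = "average")
  u <- (r - 0.5) / N
  phi1 <- sqrt(3) * (2 * u - 1)
  phi2 <- sqrt(5) * (6 * u^2 - 6 * u + 1)
  b1 <- mean(phi1[sel])
  b2 <- mean(phi2[sel])
  se <- 1 / sqrt(m)
  structure(
    list(set_name = set_name, variant = variant,
         beta_linear = b1, se_linear = se,
         p_linear = 2 * pnorm(-abs(b1 / se)),
         beta_quad = b2, se_quad = se,
         p_quad = 2 * pnorm(-abs(b2 / se)),
         p_joint = pchisq(m * (b1^2 + b2^2), df = 2, lower.tail = FALSE),
         m = m, N = N),
    class = "neyman_result"
  )
}

#' @export
print.neyman_result <- function(x, ...) {
  cat(sprintf("Neyman smooth contrast [%s, %s]: m = %d of N = %d\n",
              x$set_name, x$variant, x$m, x$N))
  cat(sprintf("  linear    beta = %6.3f  SE = %5.3f  p = %.3g\n",
              x$beta_linear, x$se_linear, x$p_linear))
  cat(sprintf("  quadratic beta = %6.3f  SE = %5.3f  p = %.3g\n",
              x$beta_quad, x$se_quad, x$p_quad))
  cat(sprintf("  joint 2-df p = %.3g\n", x$p_joint))
  invisible(x)
}

#' Neyman rank tests for a gene set over probe-level fits
#'
#' Runs [neyman_rank_test()] on the per-probe linear slopes (`raw` variant)
#' and on the slopes normalized by their SEs (`se_normalized` variant, which
#' damps the influence of noisy extreme estimates). Set membership is by
#' gene symbol at probe level.
#'
#' @param fits output of [fit_timecourse()].
#' @param annotation data.frame with `probe_id`, `symbol`.
#' @param gene_set character vector of gene symbols.
#' @param set_name label.
#' @param variants subset of `c("raw", "se_normalized")`.
#' @param require_all error (TRUE, default) or warn (FALSE) when some set
#'   symbols match no probe.
#' @param var_floor SE floor for the normalized variant.
#' @return list of `neyman_result`, one per variant.
#' @export
geneset_neyman <- function(fits, annotation, gene_set, set_name = "set",
                           variants = c("raw", "se_normalized"),
                           require_all = TRUE, var_floor = 1e-8) {
  variants <- match.arg(variants, several.ok = TRUE)
  symbols <- annotation$symbol[match(fits$probe_id, annotation$probe_id)]
  missing <- setdiff(gene_set, symbols)
  if (length(missing)) {
    msg <- paste("gene-set symbols with no probe:",
                 paste(missing, collapse = ", "))
    if (require_all) stop(msg) else warning(msg)
  }
  sel <- symbols %in% gene_set
  out <- list()
  if ("raw" %in% variants) {
    stats <- setNames(fits$beta_linear, fits$probe_id)
    out$raw <- neyman_rank_test(stats, sel, set_name, "raw")
  }
  if ("se_normalized" %in% variants) {
    stats <- setNames(fits$beta_linear / pmax(fits$se_linear, var_floor),
                      fits$probe_id)
    out$se_normalized <- neyman_rank_test(stats, sel, set_name,
                                          "se_normalized")
  }
  out
}

#' Direction consistency against literature reports
#'
#' Block-logistic regression of per-study literature direction calls
#' (up = 1) on each gene's pooled percent-per-hour rate, with
#' cluster-robust (sandwich) variance using the gene as the block: studies
#' reporting the same gene are not independent. On complete separation the
#' slope is refit by Firth-penalized likelihood and flagged. Also returns a
#' per-gene table where `consistent` means the pooled rate's sign matches
#' the majority literature direction (NA on ties).
#'
#' @param pooled data.frame with `symbol` and `rate_pct_per_hr` (e.g. from
#'   [pool_gene_rates()]).
#' @param calls literature fixture: data.frame `gene_symbol`, `study_id`,
#'   `direction` in up/down (see [read_literature_calls()]).
#' @return list of class `consistency_result`: slope, se, p, penalized,
#'   n_genes, n_reports, missing_genes, genes (per-gene table).
#' @export
direction_consistency <- function(pooled, calls) {
  calls$rate <- pooled$rate_pct_per_hr[match(calls$gene_symbol,
                                             pooled$symbol)]
  missing_genes <- sort(unique(calls$gene_symbol[is.na(calls$rate)]))
  if (length(missing_genes)) {
    message("genes without a pooled rate (dropped): ",
            paste(missing_genes, collapse = ", "))
  }
  d <- calls[!is.na(calls$rate), , drop = FALSE]
  if (!nrow(d)) stop("no literature calls match the pooled rates")
  d$y <- as.integer(d$direction == "up")

  penalized <- FALSE
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ rate, family = binomial(), data = d),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  if (sep || !fit$converged || any(abs(coef(fit)) > 15)) {
    penalized <- TRUE
    warning("complete or quasi-complete separation; ",
            "reporting Firth-penalized fit")
    X <- cbind(1, d$rate)
    ff <- firth_logistic(X, d$y)
    slope <- ff$coefficients[2]
    se <- sqrt(ff$vcov[2, 2])
  } else {
    V <- sandwich::vcovCL(fit, cluster = d$gene_symbol)
    slope <- coef(fit)["rate"]
    se <- sqrt(V["rate", "rate"])
  }
  p <- 2 * pnorm(-abs(slope / se))

  per_gene <- lapply(split(d, d$gene_symbol), function(g) {
    n_up <- sum(g$y)
    n_down <- nrow(g) - n_up
    consistent <- if (n_up == n_down) NA else {
      (g$rate[1] > 0) == (n_up > n_down)
    }
    data.frame(symbol = g$gene_symbol[1], rate_pct_per_hr = g$rate[1],
               n_up_reports = n_up, n_down_reports = n_down,
               consistent = consistent, stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, per_gene)
  rownames(genes) <- NULL
  structure(
    list(slope = unname(slope), se = unname(se), p = unname(p),
         penalized = penalized, n_genes = nrow(genes), n_reports = nrow(d),
         missing_genes = missing_genes, genes = genes),
    class = "consistency_result"
  )
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf(
    "block-logistic direction consistency: slope = %.4f (SE %.4f), p = %.3g%s\n",
    x$slope, x$se, x$p, if (x$penalized) " [Firth-penalized]" else ""))
  n_cons <- sum(x$genes$consistent, na.rm = TRUE)
  cat(sprintf("  %d/%d genes direction-consistent (%d reports, %d ties)\n",
              n_cons, x$n_genes, x$n_reports,
              sum(is.na(x$genes$consistent))))
  invisible(x)
}
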
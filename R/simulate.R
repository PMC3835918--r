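#' Configuration for the synthetic bead-array generator
#'
#' Defaults emulate the study design this package targets: 2 tumor types
#' (HCC, LC) x 3 patients x 2 sampling sites (central/peripheral) x 4 delays
#' to cryopreservation (5, 15, 30, 120 min; 5 min is the reference), 48,783
#' probes with 1-3 probes per gene, multiplicative bead-set noise whose SD is
#' proportional to the mean signal, and a truncated-normal background shared
#' by negative controls and non-expressed probes.
#'
#' @param n_probes number of array probes.
#' @param n_negative_controls number of negative-control probes per sample.
#' @param probes_per_gene integer range (each gene draws its probe count
#'   uniformly from this range).
#' @param patients_per_type patients per tumor type.
#' @param tumor_types character vector of tumor-type labels.
#' @param times_min strictly increasing delays to cryopreservation in
#'   minutes; the first value is the reference time.
#' @param sites sampling-site labels.
#' @param baseline_log_mean,baseline_log_sd location/scale of the natural-log
#'   baseline signal of expressed probes.
#' @param cv_bead coefficient of variation (SD/mean) of bead-set noise; must
#'   be positive.
#' @param background_mean,background_sd raw-scale truncated-normal background
#'   (negative controls and non-expressed probes).
#' @param frac_expressed fraction of genes expressed above background.
#' @param frac_trend fraction of probes given a genuine time trend (drawn
#'   among expressed probes).
#' @param trend_rate_pct_per_hr signed percent-per-hour effect for trend
#'   probes.
#' @param quad_frac fraction of trend probes that also get a quadratic
#'   (per hour squared) component, set to half the linear slope.
#' @param site_replicate_sd log-scale SD separating central from peripheral
#'   replicates of the same tumor.
#' @param patient_sd log-scale SD of the per-probe patient effect.
#' @param tumor_effect_sd log-scale SD of the per-probe tumor-type effect
#'   (drives the tumor-type split seen in sample clustering).
#' @param array_scale_sd log-scale SD of the per-sample array scale factor.
#' @param seed master seed; all sub-streams are derived from it
#'   deterministically.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 48783,
                       n_negative_controls = 750,
                       probes_per_gene = 1:3,
                       patients_per_type = 3,
                       tumor_types = c("HCC", "LC"),
                       times_min = c(5, 15, 30, 120),
                       sites = c("central", "peripheral"),
                       baseline_log_mean = 6.5,
                       baseline_log_sd = 1.2,
                       cv_bead = 0.2,
                       background_mean = 100,
                       background_sd = 25,
                       frac_expressed = 0.35,
                       frac_trend = 0.001,
                       trend_rate_pct_per_hr = -30,
                       quad_frac = 0.25,
                       site_replicate_sd = 0.08,
                       patient_sd = 0.3,
                       tumor_effect_sd = 0.5,
                       array_scale_sd = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_probes = n_probes, n_negative_controls = n_negative_controls,
    probes_per_gene = probes_per_gene, patients_per_type = patients_per_type,
    tumor_types = tumor_types, times_min = times_min, sites = sites,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    cv_bead = cv_bead, background_mean = background_mean,
    background_sd = background_sd, frac_expressed = frac_expressed,
    frac_trend = frac_trend, trend_rate_pct_per_hr = trend_rate_pct_per_hr,
    quad_frac = quad_frac, site_replicate_sd = site_replicate_sd,
    patient_sd = patient_sd, tumor_effect_sd = tumor_effect_sd,
    array_scale_sd = array_scale_sd, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop("configuration error: field '", field, "' ", why, call. = FALSE)
  }
  for (f in c("n_probes", "n_negative_controls", "patients_per_type")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      bad(f, "must be a positive count")
    }
  }
  if (!all(cfg$probes_per_gene >= 1) || !all(cfg$probes_per_gene <= 3)) {
    bad("probes_per_gene", "must lie in 1..3")
  }
  if (length(cfg$times_min) < 2 || any(diff(cfg$times_min) <= 0)) {
    bad("times_min", "must be strictly increasing with >= 2 values")
  }
  if (any(cfg$times_min <= 0)) bad("times_min", "must be positive")
  if (!is.numeric(cfg$cv_bead) || cfg$cv_bead <= 0) {
    bad("cv_bead", "must be > 0")
  }
  if (cfg$frac_trend < 0 || cfg$frac_trend > 1) {
    bad("frac_trend", "must lie in [0, 1]")
  }
  if (cfg$frac_expressed < 0 || cfg$frac_expressed > 1) {
    bad("frac_expressed", "must lie in [0, 1]")
  }
  if (cfg$quad_frac < 0 || cfg$quad_frac > 1) {
    bad("quad_frac", "must lie in [0, 1]")
  }
  for (f in c("baseline_log_sd", "background_mean", "background_sd")) {
    if (cfg[[f]] <= 0) bad(f, "must be > 0")
  }
  for (f in c("site_replicate_sd", "patient_sd", "tumor_effect_sd",
              "array_scale_sd")) {
    if (cfg[[f]] < 0) bad(f, "must be >= 0")
  }
  invisible(cfg)
}

# design table for a configuration (one row per sample)
sim_design <- function(cfg) {
  grid <- expand.grid(
    time_min = cfg$times_min,
    site = cfg$sites,
    patient_index = seq_len(cfg$patients_per_type),
    tumor_type = cfg$tumor_types,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$patient <- paste0(grid$tumor_type, grid$patient_index)
  grid$sample_id <- sprintf("%s_%d%s", grid$patient, grid$time_min,
                            ifelse(grid$site == "central", "C", "P"))
  n <- nrow(grid)
  grid$array_id <- paste0("A", ceiling(seq_len(n) / 12))
  grid$array_position <- paste0("pos", ((seq_len(n) - 1) %% 12) + 1)
  grid[, c("sample_id", "patient", "tumor_type", "site", "time_min",
           "array_id", "array_position")]
}

#' Generate a synthetic bead-array dataset with known ground truth
#'
#' Signals are built on the natural-log scale and exponentiated: expressed
#' probes get a log-normal baseline plus per-probe tumor-type, patient and
#' site effects, a per-sample array scale factor, and multiplicative bead
#' noise with SD = `cv_bead` x mean; trend probes additionally change
#' log-linearly (optionally quadratically) with time since the reference
#' delay. Non-expressed probes and negative controls are drawn from the same
#' truncated-normal background, so detection-call counts behave like a real
#' array where only a minority of genes is expressed. Identical
#' configurations (including the seed) give bit-identical output.
#'
#' @param config a [sim_config()].
#' @return list with `data` (an [expr_set()]) and `truth` (list of `probes`:
#'   probe_id, true_slope_per_hr, true_quad, is_trend, expressed; and
#'   `samples`: sample_id, log_scale_factor).
#' @export
simulate_dataset <- function(config) {
  cfg <- validate_sim_config(config)
  design <- sim_design(cfg)
  n <- cfg$n_probes
  ns <- nrow(design)
  t_hr <- hours(design$time_min - min(cfg$times_min))

  ## -- structure stream: gene map, expression status, effects ------------
  set.seed(component_seed(cfg$seed, 1L))
  max_genes <- ceiling(n / min(cfg$probes_per_gene)) + 1L
  sizes <- sample(cfg$probes_per_gene, max_genes, replace = TRUE)
  gene_of <- rep(seq_along(sizes), times = sizes)[seq_len(n)]
  n_genes <- max(gene_of)
  symbols <- sprintf("GENE%05d", gene_of)
  probe_ids <- sprintf("PRB%06d", seq_len(n))

  gene_expressed <- runif(n_genes) < cfg$frac_expressed
  expressed <- gene_expressed[gene_of]

  baseline <- rnorm(n, cfg$baseline_log_mean, cfg$baseline_log_sd)
  tumor_eff <- matrix(rnorm(n * length(cfg$tumor_types), 0, cfg$tumor_effect_sd),
                      n, length(cfg$tumor_types),
                      dimnames = list(NULL, cfg$tumor_types))
  patients <- unique(design$patient)
  patient_eff <- matrix(rnorm(n * length(patients), 0, cfg$patient_sd),
                        n, length(patients), dimnames = list(NULL, patients))
  series <- sample_series(design)
  series_lv <- unique(series)
  site_eff <- matrix(rnorm(n * length(series_lv), 0, cfg$site_replicate_sd),
                     n, length(series_lv), dimnames = list(NULL, series_lv))

  slope <- numeric(n)
  quad <- numeric(n)
  is_trend <- logical(n)
  n_trend <- round(cfg$frac_trend * n)
  if (n_trend > 0) {
    candidates <- which(expressed)
    n_trend <- min(n_trend, length(candidates))
    idx <- sample(candidates, n_trend)
    is_trend[idx] <- TRUE
    slope[idx] <- slope_from_rate(cfg$trend_rate_pct_per_hr)
    n_quad <- round(cfg$quad_frac * n_trend)
    if (n_quad > 0) {
      qidx <- idx[sample.int(n_trend, n_quad)]
      quad[qidx] <- slope[qidx] / 2
    }
  }

  ## -- noise stream: per-sample scale + signal matrix --------------------
  set.seed(component_seed(cfg$seed, 2L))
  log_scale <- rnorm(ns, 0, cfg$array_scale_sd)
  sigma <- sqrt(log1p(cfg$cv_bead^2))
  signal <- matrix(0, n, ns)
  exp_idx <- which(expressed)
  bg_idx <- which(!expressed)
  if (length(exp_idx)) {
    # build the signal column by column (keeps memory flat at full array size)
    for (s in seq_len(ns)) {
      lm_s <- baseline[exp_idx] +
        tumor_eff[exp_idx, design$tumor_type[s]] +
        patient_eff[exp_idx, design$patient[s]] +
        site_eff[exp_idx, series[s]] +
        slope[exp_idx] * t_hr[s] + quad[exp_idx] * t_hr[s]^2 +
        log_scale[s]
      noise <- rnorm(length(exp_idx), -sigma^2 / 2, sigma)
      signal[exp_idx, s] <- exp(lm_s + noise)
    }
  }
  if (length(bg_idx)) {
    signal[bg_idx, ] <- rtruncnorm_lower(length(bg_idx) * ns,
                                         cfg$background_mean,
                                         cfg$background_sd, lower = 1)
  }

  ## -- negative-control stream -------------------------------------------
  set.seed(component_seed(cfg$seed, 3L))
  negatives <- matrix(
    rtruncnorm_lower(cfg$n_negative_controls * ns, cfg$background_mean,
                     cfg$background_sd, lower = 1),
    cfg$n_negative_controls, ns
  )
  rownames(negatives) <- sprintf("NEG%04d", seq_len(cfg$n_negative_controls))

  ## -- bead-set SD stream (within-array replicate-bead spread) -----------
  set.seed(component_seed(cfg$seed, 4L))
  bead_df <- 14 # ~15 beads per probe on a typical array
  bead_sd <- cfg$cv_bead * signal *
    sqrt(matrix(rchisq(n * ns, bead_df), n, ns) / bead_df)

  ## -- RIN: stable over time, lower for the second tumor type ------------
  set.seed(component_seed(cfg$seed, 5L))
  rin <- rnorm(ns, 7.3, 0.5) -
    0.9 * (design$tumor_type == cfg$tumor_types[min(2, length(cfg$tumor_types))] &
             length(cfg$tumor_types) > 1)
  rin <- round(pmin(10, pmax(1, rin)), 1)

  samples <- cbind(design[, "sample_id", drop = FALSE],
                   design[, c("patient", "tumor_type", "site", "time_min")],
                   rin = rin,
                   design[, c("array_id", "array_position")])
  probes <- data.frame(probe_id = probe_ids, symbol = symbols,
                       stringsAsFactors = FALSE)
  es <- expr_set(signal, negatives, probes, samples, bead_sd = bead_sd)
  truth <- list(
    probes = data.frame(probe_id = probe_ids,
                        true_slope_per_hr = slope,
                        true_quad = quad,
                        is_trend = is_trend,
                        expressed = expressed,
                        stringsAsFactors = FALSE),
    samples = data.frame(sample_id = samples$sample_id,
                         log_scale_factor = log_scale,
                         stringsAsFactors = FALSE)
  )
  list(data = es, truth = truth)
}

#' Inject a log-linear time signature into chosen genes
#'
#' Multiplies the signal of every probe of the named genes by
#' `exp(beta * (t - t_ref))` with `beta = log1p(rate/100)` per hour, leaving
#' the reference-time samples untouched. Other probes are unchanged; repeated
#' injections into disjoint gene sets compose independently.
#'
#' @param es an [expr_set()].
#' @param gene_symbols genes to perturb; all must exist in the annotation.
#' @param rate_pct_per_hr signed percent-per-hour rate (0 leaves `es`
#'   unchanged).
#' @return the modified `expr_set`.
#' @export
inject_signature <- function(es, gene_symbols, rate_pct_per_hr) {
  missing <- setdiff(gene_symbols, es$probes$symbol)
  if (length(missing)) {
    stop("unknown gene symbols: ", paste(missing, collapse = ", "))
  }
  beta <- slope_from_rate(rate_pct_per_hr)
  dt <- hours(es$samples$time_min - min(es$samples$time_min))
  rows <- es$probes$symbol %in% gene_symbols
  es$signal[rows, ] <- es$signal[rows, , drop = FALSE] *
    matrix(exp(beta * dt), sum(rows), length(dt), byrow = TRUE)
  if (!is.null(es$bead_sd)) {
    es$bead_sd[rows, ] <- es$bead_sd[rows, , drop = FALSE] *
      matrix(exp(beta * dt), sum(rows), length(dt), byrow = TRUE)
  }
  es
}
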
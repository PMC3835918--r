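# shared fixture factories; all synthetic, built at test time

small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_probes = 600, n_negative_controls = 200, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# minimal hand-built expression set: deterministic values, no RNG
tiny_expr_set <- function(n_probes = 6, times = c(5, 15, 30, 120),
                          signal = NULL) {
  design <- expand.grid(time_min = times, site = c("central", "peripheral"),
                        stringsAsFactors = FALSE)
  design$patient <- "HCC1"
  design$tumor_type <- "HCC"
  design$sample_id <- sprintf("HCC1_%d%s", design$time_min,
                              ifelse(design$site == "central", "C", "P"))
  design$rin <- 7.5
  design$array_id <- "A1"
  design$array_position <- paste0("pos", seq_len(nrow(design)))
  ns <- nrow(design)
  if (is.null(signal)) {
    signal <- matrix(100 + outer(seq_len(n_probes), seq_len(ns)),
                     n_probes, ns)
  }
  probes <- data.frame(
    probe_id = sprintf("PRB%03d", seq_len(n_probes)),
    symbol = sprintf("GENE%03d", rep(seq_len(ceiling(n_probes / 2)),
                                     each = 2)[seq_len(n_probes)]),
    stringsAsFactors = FALSE
  )
  negatives <- matrix(90, 30, ns,
                      dimnames = list(sprintf("NEG%02d", 1:30), NULL))
  expr_set(signal, negatives, probes,
           design[, c("sample_id", "patient", "tumor_type", "site",
                      "time_min", "rin", "array_id", "array_position")])
}

# full-factorial design table without signals, for regression-model tests
design_table <- function(times = c(5, 15, 30, 120), patients = 3,
                         types = c("HCC", "LC")) {
  sim_design(sim_config(times_min = times, patients_per_type = patients,
                        tumor_types = types))
}

# sim_design is internal; reach it for test fixtures only
sim_design <- getFromNamespace("sim_design", "warmclock")

subset_samples_for_test <- function(es, keep) {
  expr_set(es$signal[, keep, drop = FALSE], es$negatives[, keep, drop = FALSE],
           es$probes, es$samples[keep, , drop = FALSE])
}
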
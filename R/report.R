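#' Assemble the run report
#'
#' Writes one deterministic set of plain-text files aggregating all pipeline
#' outputs: the per-sample QC table, the overall-trend table, the
#' significant-gene table per tumor type (types without results are marked
#' absent rather than dropped), the gene-set smooth-contrast and
#' direction-consistency tables, the sample dendrogram (newick) and the
#' fold-change outlier summary. Re-running on identical inputs reproduces
#' the files byte for byte.
#'
#' @param results named list with elements `qc` (from [qc_report()]),
#'   `overall_trend` (from [overall_trend_table()]), `significant_genes`
#'   (named list per tumor type, each from [significant_genes()] or NULL),
#'   `geneset_neyman` (list of `neyman_result`), `geneset_consistency`
#'   (a `consistency_result` or NULL), `dendrogram` (from
#'   [hierarchical_cluster()]), `fold_change` (from
#'   [fold_change_outliers()]).
#' @param dir output directory.
#' @return invisibly, the written file paths.
#' @export
build_report <- function(results, dir) {
  required <- c(qc = "qc", overall_trend = "trend",
                significant_genes = "timecourse", geneset_neyman = "geneset",
                geneset_consistency = "geneset", dendrogram = "cluster",
                fold_change = "cluster")
  for (nm in names(required)) {
    if (!nm %in% names(results)) {
      stop("report input '", nm, "' missing; rerun the ", required[[nm]],
           " stage")
    }
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- list(qc_samples = results$qc$samples,
                 overall_trend = results$overall_trend)

  sig <- results$significant_genes
  sig_rows <- lapply(names(sig), function(tt) {
    tab <- sig[[tt]]
    if (is.null(tab)) {
      return(data.frame(tumor_type = tt, symbol = NA_character_,
                        q = NA_real_, rate_pct_per_hr = NA_real_,
                        direction = "absent", stringsAsFactors = FALSE))
    }
    if (!nrow(tab)) {
      return(data.frame(tumor_type = tt, symbol = NA_character_,
                        q = NA_real_, rate_pct_per_hr = NA_real_,
                        direction = "none", stringsAsFactors = FALSE))
    }
    data.frame(tumor_type = tt, symbol = tab$symbol, q = tab$q,
               rate_pct_per_hr = tab$rate_pct_per_hr,
               direction = tab$direction, stringsAsFactors = FALSE)
  })
  tables$significant_genes <- do.call(rbind, sig_rows)

  ney <- results$geneset_neyman
  tables$geneset_neyman <- do.call(rbind, lapply(ney, function(x) {
    data.frame(set_name = x$set_name, variant = x$variant,
               beta_linear = x$beta_linear, se_linear = x$se_linear,
               p_linear = x$p_linear, beta_quad = x$beta_quad,
               se_quad = x$se_quad, p_quad = x$p_quad, p_joint = x$p_joint,
               m = x$m, N = x$N, stringsAsFactors = FALSE)
  }))

  cons <- results$geneset_consistency
  if (is.null(cons)) {
    tables$geneset_consistency <- data.frame(
      slope = NA_real_, se = NA_real_, p = NA_real_, penalized = NA,
      n_genes = 0L, n_reports = 0L)
    tables$consistency_genes <- data.frame(
      symbol = character(0), rate_pct_per_hr = numeric(0),
      n_up_reports = integer(0), n_down_reports = integer(0),
      consistent = logical(0))
  } else {
    tables$geneset_consistency <- data.frame(
      slope = cons$slope, se = cons$se, p = cons$p,
      penalized = cons$penalized, n_genes = cons$n_genes,
      n_reports = cons$n_reports)
    tables$consistency_genes <- cons$genes
  }

  tables$fold_change <- results$fold_change
  paths <- suppressMessages(write_results(tables, dir))
  nwk <- file.path(dir, "dendrogram.nwk")
  dendrogram_newick(results$dendrogram, nwk)
  paths <- c(paths, nwk)
  message("report written to ", dir, " (", length(paths), " files)")
  invisible(paths)
}
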
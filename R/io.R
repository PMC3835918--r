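#' Write an expression set to disk
#'
#' The expression table uses a GenomeStudio-style sample-probe-profile
#' dialect: a header row `PROBE_ID SYMBOL <sample>.AVG_Signal
#' [<sample>.BEAD_STDERR] [<sample>.Detection_Pval]`, tab-separated, UTF-8,
#' '.' decimal, empty fields for missing values. Negative controls go to a
#' companion TSV with the same sample columns; the sample design to a CSV.
#'
#' @param es an [expr_set()].
#' @param expr_path path for the expression TSV.
#' @param controls_path path for the negative-control TSV.
#' @param meta_path path for the sample-metadata CSV.
#' @param detection optional probes x samples detection p-value matrix to
#'   embed as `Detection_Pval` columns.
#' @return invisibly, the three paths.
#' @export
write_expression <- function(es, expr_path, controls_path, meta_path,
                             detection = NULL) {
  ns <- ncol(es$signal)
  ids <- es$samples$sample_id
  df <- data.frame(PROBE_ID = es$probes$probe_id,
                   SYMBOL = es$probes$symbol,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_len(ns)) {
    df[[paste0(ids[j], ".AVG_Signal")]] <- es$signal[, j]
    if (!is.null(es$bead_sd)) {
      df[[paste0(ids[j], ".BEAD_STDERR")]] <- es$bead_sd[, j]
    }
    if (!is.null(detection)) {
      df[[paste0(ids[j], ".Detection_Pval")]] <- detection[, j]
    }
  }
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  ctl <- data.frame(PROBE_ID = rownames(es$negatives),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_len(ns)) {
    ctl[[paste0(ids[j], ".AVG_Signal")]] <- es$negatives[, j]
  }
  write.table(ctl, controls_path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  write.table(es$samples, meta_path, sep = ",", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8", na = "")
  message("wrote ", nrow(df), " probes x ", ns, " samples to ", expr_path)
  invisible(c(expr_path, controls_path, meta_path))
}

# parse "<sample>.AVG_Signal" columns out of a profile table
signal_columns <- function(nms, suffix = ".AVG_Signal") {
  hit <- grepl(paste0("\\", suffix, "$"), nms)
  list(idx = which(hit), ids = sub(paste0("\\", suffix, "$"), "", nms[hit]))
}

#' Read an expression set written by [write_expression()]
#'
#' Round-trips bit-exactly for finite values; sample order follows the
#' metadata CSV. Fails with the offending line/sample named on negative
#' signals, duplicate probe ids, or samples present in the metadata but
#' absent from the expression table.
#'
#' @inheritParams write_expression
#' @return an [expr_set()].
#' @export
read_expression <- function(expr_path, controls_path, meta_path) {
  for (p in c(expr_path, controls_path, meta_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  tab <- read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("PROBE_ID", "SYMBOL") %in% names(tab))) {
    stop("parse error in ", expr_path,
         ": header must contain PROBE_ID and SYMBOL")
  }
  if (anyDuplicated(tab$PROBE_ID)) {
    line <- which(duplicated(tab$PROBE_ID))[1] + 1L
    stop("parse error in ", expr_path, " line ", line,
         ": duplicate probe id ", tab$PROBE_ID[line - 1L])
  }
  sig_cols <- signal_columns(names(tab))
  if (!length(sig_cols$idx)) {
    stop("parse error in ", expr_path, ": no AVG_Signal columns")
  }
  signal <- as.matrix(tab[, sig_cols$idx, drop = FALSE])
  if (any(signal < 0, na.rm = TRUE)) {
    bad <- which(rowSums(signal < 0) > 0)[1] + 1L
    stop("parse error in ", expr_path, " line ", bad,
         ": negative AVG_Signal")
  }
  colnames(signal) <- sig_cols$ids

  bs_cols <- signal_columns(names(tab), ".BEAD_STDERR")
  bead_sd <- NULL
  if (length(bs_cols$idx)) {
    bead_sd <- as.matrix(tab[, bs_cols$idx, drop = FALSE])
    colnames(bead_sd) <- bs_cols$ids
  }

  ctl <- read.delim(controls_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  ctl_cols <- signal_columns(names(ctl))
  negatives <- as.matrix(ctl[, ctl_cols$idx, drop = FALSE])
  colnames(negatives) <- ctl_cols$ids
  rownames(negatives) <- ctl$PROBE_ID

  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient", "tumor_type", "site", "time_min")
  if (!all(need %in% names(meta))) {
    stop("parse error in ", meta_path, ": missing columns ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  }
  if (!"rin" %in% names(meta)) meta$rin <- NA_real_
  if (!"array_id" %in% names(meta)) meta$array_id <- "A1"
  if (!"array_position" %in% names(meta)) meta$array_position <- "pos1"
  absent <- setdiff(meta$sample_id, colnames(signal))
  if (length(absent)) {
    stop("sample(s) in metadata but absent from expression table: ",
         paste(absent, collapse = ", "))
  }
  absent_ctl <- setdiff(meta$sample_id, colnames(negatives))
  if (length(absent_ctl)) {
    stop("sample(s) in metadata but absent from control table: ",
         paste(absent_ctl, collapse = ", "))
  }
  ord <- meta$sample_id
  message("read ", nrow(tab), " probes x ", length(ord), " samples from ",
          expr_path)
  expr_set(signal[, ord, drop = FALSE],
           negatives[, ord, drop = FALSE],
           data.frame(probe_id = tab$PROBE_ID, symbol = tab$SYMBOL,
                      stringsAsFactors = FALSE),
           meta,
           bead_sd = if (!is.null(bead_sd)) bead_sd[, ord, drop = FALSE])
}

#' Read a gene set (one symbol per line)
#'
#' Blank lines and surrounding whitespace are ignored; duplicate symbols are
#' dropped with a warning.
#'
#' @param path text file, one gene symbol per line.
#' @param set_name label for the set (defaults to the file name).
#' @return character vector of unique symbols with attribute `set_name`.
#' @export
read_gene_set <- function(path, set_name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty gene-set file: ", path)
  if (anyDuplicated(lines)) {
    dup <- unique(lines[duplicated(lines)])
    warning("duplicate symbols de-duplicated in ", path, ": ",
            paste(dup, collapse = ", "))
    lines <- unique(lines)
  }
  structure(lines, set_name = set_name %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a literature direction-call fixture
#'
#' CSV with columns `gene_symbol, study_id, direction`; `direction` must be
#' `up` or `down`. One row per (gene, study) report.
#'
#' @param path CSV file path.
#' @return data.frame with those three columns.
#' @export
read_literature_calls <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene_symbol", "study_id", "direction")
  if (!all(need %in% names(df))) {
    stop("parse error in ", path, ": need columns ",
         paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$direction), c("up", "down"))
  if (length(bad)) {
    stop("unknown direction token(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  }
  if (!nrow(df)) stop("empty literature fixture: ", path)
  df
}

#' Write result tables as TSVs with stable column order
#'
#' @param tables named list of data.frames.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_results <- function(tables, dir) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8", na = "")
    message("wrote ", nrow(tables[[nm]]), " rows to ", p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write / read a ground-truth table
#' @param truth the `truth` element of [simulate_dataset()].
#' @param path TSV path.
#' @return `write_ground_truth` invisibly returns `path`;
#'   `read_ground_truth` returns the probe-level truth data.frame.
#' @export
write_ground_truth <- function(truth, path) {
  write.table(truth$probes, path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
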
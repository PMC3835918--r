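#' Hierarchical clustering of samples (centred correlation, average linkage)
#'
#' Pairwise sample distance is 1 - Pearson correlation of log-expression
#' (the "centred correlation" convention: each sample vector is mean-
#' centered, which Pearson's r does by definition), merged by average
#' linkage (UPGMA). Ties break deterministically because samples enter in
#' label order.
#'
#' @param log_expr probes x samples log-expression matrix (>= 2 samples),
#'   typically the quantile-normalized matrix.
#' @return list of class `sample_dendrogram`: `hclust` (the merge tree),
#'   `dist` (the distance object), `labels`.
#' @export
hierarchical_cluster <- function(log_expr) {
  if (ncol(log_expr) < 2) stop("need >= 2 samples")
  sds <- matrixStats::colSds(log_expr)
  if (any(sds == 0)) {
    stop("zero-variance sample(s): ",
         paste(colnames(log_expr)[sds == 0], collapse = ", "))
  }
  d <- as.dist(1 - cor(log_expr))
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, dist = d, labels = colnames(log_expr)),
            class = "sample_dendrogram")
}

#' @export
print.sample_dendrogram <- function(x, ...) {
  cat("sample dendrogram:", length(x$labels),
      "leaves, average linkage on 1 - Pearson r\n")
  invisible(x)
}

#' Export a dendrogram as a newick string
#'
#' Merge heights become branch lengths, so the tree round-trips through any
#' newick-aware tool.
#'
#' @param dendro a [hierarchical_cluster()] result.
#' @param path optional file to write to.
#' @return the newick string, invisibly if written to `path`.
#' @export
dendrogram_newick <- function(dendro, path = NULL) {
  phy <- ape::as.phylo(dendro$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Two-group split of the dendrogram
#'
#' Cuts the tree into two clusters (the top split) and returns the cluster
#' membership, for comparison with known sample labels.
#'
#' @param dendro a [hierarchical_cluster()] result.
#' @param k number of clusters.
#' @return named integer vector of cluster ids.
#' @export
cut_dendrogram <- function(dendro, k = 2) {
  stats::cutree(dendro$hclust, k = k)
}

#' Rand index between two partitions
#'
#' Fraction of sample pairs on which two partitions agree (both together or
#' both apart); 1 means identical partitions up to labeling.
#'
#' @param a,b partition label vectors of equal length.
#' @return Rand index in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  idx <- upper.tri(same_a)
  mean(same_a[idx] == same_b[idx])
}

#' Fold-change outlier counts against the reference time
#'
#' For every tissue series, counts the probes whose (normalized-scale)
#' log expression differs from the same series' reference-time sample by
#' more than `fold` in either direction, per later time point. Comparing the
#' reference sample to itself gives 0; direction is symmetric by
#' construction.
#'
#' @param log_expr probes x samples log-expression matrix (natural log,
#'   quantile-normalized scale).
#' @param samples matching sample design table.
#' @param reference_time reference delay (minutes).
#' @param fold linear-scale fold-change cutoff.
#' @param pool_sites see [sample_series()].
#' @return data.frame: series, time_min, sample_id, reference_id, n_outliers.
#' @export
fold_change_outliers <- function(log_expr, samples, reference_time = 5,
                                 fold = 2, pool_sites = FALSE) {
  series <- sample_series(samples, pool_sites = pool_sites)
  cut <- log(fold)
  out <- list()
  for (sr in unique(series)) {
    idx <- which(series == sr)
    ref <- idx[samples$time_min[idx] == reference_time]
    if (!length(ref)) {
      warning("series ", sr, " lacks a t", reference_time,
              " sample; skipped")
      next
    }
    ref <- ref[1]
    for (j in idx) {
      out[[length(out) + 1L]] <- data.frame(
        series = sr,
        time_min = samples$time_min[j],
        sample_id = samples$sample_id[j],
        reference_id = samples$sample_id[ref],
        n_outliers = sum(abs(log_expr[, j] - log_expr[, ref]) > cut),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res[order(res$series, res$time_min), , drop = FALSE]
}
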
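#' Per-cluster motif enrichment against the genome background
#'
#' The mean number of sites per gene in the cluster is normalized to the
#' mean over the whole genome gene set and reported as a percent deviation,
#' `(cluster_mean / genome_mean - 1) * 100`. Significance of the difference
#' in means is assessed with a two-sided Welch (heteroscedastic) t-test of
#' the cluster's per-gene counts against the whole-genome per-gene counts.
#'
#' @param counts Named numeric vector of per-gene site counts over the
#'   genome gene universe (one motif), e.g. one column of
#'   [site_count_matrix()].
#' @param cluster_genes Character vector of gene ids (subset of
#'   `names(counts)`, >= 2 for the t-test).
#' @param exclude_cluster_from_background If `TRUE`, the comparison group is
#'   the genome minus the cluster; default `FALSE` compares against the
#'   whole genome including the cluster (as the genome-mean normalization
#'   implies).
#' @return List with `cluster_mean`, `genome_mean`, `enrichment_pct`, `p`,
#'   `significance` (`""`, `"*"` p<0.1, `"**"` p<0.05), `n_cluster`,
#'   `n_genome`.
#' @export
cluster_enrichment <- function(counts, cluster_genes,
                               exclude_cluster_from_background = FALSE) {
  if (is.null(names(counts)))
    stop("`counts` must be named by gene id", call. = FALSE)
  miss <- setdiff(cluster_genes, names(counts))
  if (length(miss))
    stop("cluster gene(s) without counts: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(cluster_genes) < 2L)
    stop("cluster must contain >= 2 genes for the t-test", call. = FALSE)
  x <- counts[cluster_genes]
  bg <- if (exclude_cluster_from_background)
    counts[setdiff(names(counts), cluster_genes)] else counts
  genome_mean <- mean(counts)
  if (genome_mean == 0)
    stop("genome mean is 0: enrichment undefined", call. = FALSE)
  cluster_mean <- mean(x)
  pct <- (cluster_mean / genome_mean - 1) * 100
  p <- if (stats::var(x) == 0 && stats::var(bg) == 0) {
    if (mean(x) == mean(bg)) 1 else 0
  } else {
    stats::t.test(x, bg, var.equal = FALSE)$p.value
  }
  sig <- if (p < 0.05) "**" else if (p < 0.1) "*" else ""
  list(cluster_mean = cluster_mean, genome_mean = genome_mean,
       enrichment_pct = pct, p = p, significance = sig,
       n_cluster = length(x), n_genome = length(bg))
}

#' Cluster-by-motif enrichment table
#'
#' Builds the classical promoter-analysis summary: rows are clusters,
#' columns are motifs/dyads, cells are percent enrichment over the genome
#' mean with significance stars, plus the genome mean per motif.
#'
#' @param count_matrix Gene x motif count matrix over the genome universe
#'   (see [site_count_matrix()]).
#' @param assignments data.frame with `gene_id` and `label` (e.g. from
#'   [assign_clusters()]).
#' @param ... Passed to [cluster_enrichment()].
#' @return data.frame with one row per (cluster, motif): `label`, `motif`,
#'   `cluster_mean`, `genome_mean`, `enrichment_pct`, `p`, `significance`.
#' @export
enrichment_table <- function(count_matrix, assignments, ...) {
  labs <- sort(unique(assignments$label))
  rows <- list()
  for (lab in labs) {
    genes <- assignments$gene_id[assignments$label == lab]
    genes <- intersect(genes, rownames(count_matrix))
    if (length(genes) < 2L) next
    for (m in colnames(count_matrix)) {
      e <- cluster_enrichment(stats::setNames(count_matrix[, m],
                                              rownames(count_matrix)),
                              genes, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        label = lab, motif = m,
        cluster_mean = e$cluster_mean, genome_mean = e$genome_mean,
        enrichment_pct = e$enrichment_pct, p = e$p,
        significance = e$significance, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
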
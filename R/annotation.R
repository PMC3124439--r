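#' Hypergeometric category over-representation for a gene cluster
#'
#' For every functional category represented in the cluster, computes the
#' exact upper-tail probability P(X >= k) of drawing k or more
#' category members in a sample of n genes from a universe of N genes of
#' which K carry the category (sampling without replacement). In GO mode the
#' p-values are additionally BH-adjusted across the tested categories.
#' Categories absent from the cluster (k = 0) are not tested.
#'
#' @param cluster_genes Character vector of gene ids.
#' @param annotations data.frame with columns `gene_id`, `category_id` and
#'   optionally `namespace` (see [read_annotation_table()]); one row per
#'   gene-category link.
#' @param mode `"funcat"` (no multiple-testing adjustment reported) or
#'   `"go"` (BH adjustment across categories).
#' @param universe `"annotated"` (default): N = genes with at least one
#'   annotation, and only annotated cluster genes enter n; `"all"`: N
#'   covers `universe_genes`.
#' @param universe_genes Character vector of all genome genes (required for
#'   `universe = "all"`).
#' @return data.frame with `category`, `k`, `n`, `K`, `N`, `ratio`
#'   (observed/expected), `p`, and `p_adj` (GO mode), sorted by `p`.
#' @export
hypergeom_enrich <- function(cluster_genes, annotations,
                             mode = c("funcat", "go"),
                             universe = c("annotated", "all"),
                             universe_genes = NULL) {
  mode <- match.arg(mode)
  universe <- match.arg(universe)
  if (!all(c("gene_id", "category_id") %in% names(annotations)))
    stop("annotations need columns 'gene_id' and 'category_id'",
         call. = FALSE)
  cluster_genes <- unique(as.character(cluster_genes))
  ann_genes <- unique(annotations$gene_id)
  if (universe == "annotated") {
    uni <- ann_genes
    cluster_in <- intersect(cluster_genes, uni)
  } else {
    if (is.null(universe_genes))
      stop("`universe_genes` required for universe = 'all'", call. = FALSE)
    uni <- unique(as.character(universe_genes))
    extra <- setdiff(ann_genes, uni)
    if (length(extra))
      stop("annotated gene(s) outside the universe: ",
           paste(utils::head(extra, 3), collapse = ", "), call. = FALSE)
    cluster_in <- intersect(cluster_genes, uni)
  }
  out_of_uni <- setdiff(cluster_genes, uni)
  if (length(out_of_uni) && universe == "all")
    stop("cluster gene(s) outside the universe: ",
         paste(utils::head(out_of_uni, 3), collapse = ", "), call. = FALSE)
  N <- length(uni)
  n <- length(cluster_in)
  if (n == 0L)
    return(data.frame(category = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      ratio = numeric(0), p = numeric(0),
                      stringsAsFactors = FALSE))
  ann <- annotations[annotations$gene_id %in% uni, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "category_id")])
  Ktab <- table(ann$category_id)
  hit <- ann[ann$gene_id %in% cluster_in, , drop = FALSE]
  ktab <- table(hit$category_id)
  cats <- names(ktab)
  k <- as.integer(ktab)
  K <- as.integer(Ktab[cats])
  if (any(k > K) || n > N)
    stop("inconsistent annotation margins (k > K or n > N)", call. = FALSE)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(category = cats, k = k, n = n, K = K, N = N,
                    ratio = (k / n) / (K / N), p = p,
                    stringsAsFactors = FALSE)
  if (mode == "go") out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a gene-to-category annotation table
#'
#' TSV with columns `gene_id`, `category_id`, and optionally `namespace`
#' (e.g. "funcat" or "go").
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "category_id") %in% names(df)))
    stop("annotation table ", path,
         " needs columns 'gene_id' and 'category_id'", call. = FALSE)
  df
}
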
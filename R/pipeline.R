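#' Cluster accounting summary
#'
#' From a complete assignment over labels A-H and X, reports per-cluster
#' counts and the derived behaviour-group sums: regulator-repressed
#' (C + E + G + H), regulator-induced (D + F), growth-rate-only (A + B),
#' the heterogeneous remainder X, the total regulated by the repressor
#' (total - growth-rate-only), and each as a percent of the total rounded
#' to one decimal.
#'
#' @param assignments Either a data.frame with `gene_id` and `label`
#'   columns, or a named integer vector of per-label counts.
#' @return List with `counts` (named vector over A-H, X), `total`,
#'   `repressed`, `induced`, `growth_rate_only`, `x`, `cre1_regulated`,
#'   and `percent` (named vector of the same sums as % of total, one
#'   decimal).
#' @examples
#' report_accounting(c(A = 19, B = 24, C = 16, D = 36, E = 50, F = 36,
#'                     G = 26, H = 26, X = 17))
#' @export
report_accounting <- function(assignments) {
  if (is.data.frame(assignments)) {
    if (!nrow(assignments)) stop("empty assignment table", call. = FALSE)
    counts_tab <- table(assignments$label)
    counts <- stats::setNames(rep(0L, 9L), c(LETTERS[1:8], "X"))
    counts[names(counts_tab)] <- as.integer(counts_tab)
  } else {
    counts <- stats::setNames(rep(0L, 9L), c(LETTERS[1:8], "X"))
    known <- intersect(names(assignments), names(counts))
    counts[known] <- as.integer(assignments[known])
  }
  if (!length(counts) || sum(counts) == 0L)
    stop("no cluster counts to account for", call. = FALSE)
  miss <- names(counts)[counts == 0L & names(counts) %in% LETTERS[1:8]]
  if (length(miss) == 8L)
    stop("assignment contains none of the labels A-H", call. = FALSE)
  total <- sum(counts)
  repressed <- sum(counts[c("C", "E", "G", "H")])
  induced <- sum(counts[c("D", "F")])
  gr_only <- sum(counts[c("A", "B")])
  x <- counts[["X"]]
  regulated <- total - gr_only
  pct <- round(100 * c(repressed = repressed, induced = induced,
                       growth_rate_only = gr_only, x = x,
                       cre1_regulated = regulated) / total, 1)
  list(counts = counts, total = total, repressed = repressed,
       induced = induced, growth_rate_only = gr_only, x = x,
       cre1_regulated = regulated, percent = pct)
}

#' Cluster sizes reported in the original regulon-mapping study
#'
#' The published per-cluster sizes of the 250 strongly regulated genes
#' (clusters A-H; X obtained by subtraction from the total). Used as a
#' fixture for the accounting arithmetic.
#'
#' @return Named integer vector over A-H, X summing to 250.
#' @export
published_cluster_sizes <- function() {
  path <- system.file("extdata", "cre1_cluster_sizes.tsv",
                      package = "cremap", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$n_genes), df$label)
}

#' Run the full pipeline on simulated or provided inputs
#'
#' Executes simulate -> pretreat -> moderated tests -> regulated-gene
#' selection -> cluster assignment -> promoter motif scan & enrichment ->
#' category enrichment, writing every stage hand-off as TSV plus a JSON
#' manifest.
#'
#' @param config Either a [simulation_config()] (simulated run) or the path
#'   to a YAML file with a `simulate:` section of `simulation_config()` /
#'   [demo_config()] arguments.
#' @param outdir Output directory (created if needed).
#' @param alpha,lfc_threshold Regulated-gene selection cutoffs.
#' @param cast_threshold CAST affinity threshold.
#' @param mode Template-matching correlation mode; the demo design contains
#'   mirrored behaviour classes, so `"signed"` is used here.
#' @param motifs Named list of motifs/dyads to scan (default: the repressor
#'   consensus, its reverse complement, and the three dyads at 20/50 bp).
#' @param seeds_per_cluster Seed genes taken per planted cluster from the
#'   simulation truth (default 8; seed groups emulate curated behaviour groups); for non-simulated runs supply `seeds`.
#' @param seeds Optional named list label -> gene ids overriding the
#'   truth-derived seeds.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, outdir, alpha = 0.05, lfc_threshold = 2,
                         cast_threshold = 0.8, mode = "signed",
                         motifs = NULL, seeds_per_cluster = 8L,
                         seeds = NULL) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(motifs)) {
    motifs <- list(
      SYGGRG = "SYGGRG",
      CYCCRS = "CYCCRS",
      SYGGRG_CYCCRS_20 = dyad_spec("SYGGRG", "CYCCRS", 20),
      SYGGRG_SYGGRG_20 = dyad_spec("SYGGRG", "SYGGRG", 20),
      SYGGRG_SYGGRG_50 = dyad_spec("SYGGRG", "SYGGRG", 50)
    )
  }
  sim <- simulate_experiment(config)
  for (nm in names(sim$arrays))
    write_gpr_table(sim$arrays[[nm]], file.path(outdir,
                                                paste0(nm, ".gpr.tsv")))
  ratios <- lapply(sim$arrays, function(a) {
    a$ch1 <- a$F635_mean; a$ch2 <- a$F532_mean
    a$in_coding_on_matching_strand <-
      as.logical(a$in_coding_on_matching_strand)
    preprocess_array(a)$ratios
  })
  results <- do.call(rbind, lapply(1:4, function(k) {
    fit_moderated(ratios[paste0("c", k, "_r", 1:2)],
                  orientation = sim$orientation,
                  comparison_id = paste0("c", k))
  }))
  utils::write.table(results, file.path(outdir, "moderated_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sel <- select_regulated(results, alpha = alpha,
                          lfc_threshold = lfc_threshold)
  utils::write.table(
    data.frame(gene_id = rownames(sel$profiles), sel$profiles),
    file.path(outdir, "regulated_profiles.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (is.null(seeds)) {
    membership <- sim$truth$cluster_membership
    labs <- setdiff(sort(unique(membership)), c("none", "X"))
    seeds <- lapply(stats::setNames(labs, labs), function(lab) {
      g <- intersect(names(membership)[membership == lab], sel$genes)
      utils::head(g, seeds_per_cluster)
    })
    seeds <- seeds[vapply(seeds, length, 1L) >= 2L]
  }
  assignments <- assign_clusters(sel$profiles, seeds, mode = mode,
                                 cast_threshold = cast_threshold)
  utils::write.table(assignments, file.path(outdir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  prom <- simulate_promoters(config)
  Biostrings::writeXStringSet(prom$promoters,
                              file.path(outdir, "promoters.fasta"))
  counts <- site_count_matrix(motifs, prom$promoters)
  utils::write.table(data.frame(gene_id = rownames(counts), counts),
                     file.path(outdir, "site_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  enr <- enrichment_table(counts, assignments)
  utils::write.table(enr, file.path(outdir, "motif_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- simulate_annotations(config, enriched_category = "cat_planted",
                              enriched_cluster = "E")
  utils::write.table(ann, file.path(outdir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat_enr <- do.call(rbind, lapply(
    sort(unique(assignments$label)), function(lab) {
      g <- assignments$gene_id[assignments$label == lab]
      e <- hypergeom_enrich(g, ann, mode = "funcat")
      if (nrow(e)) cbind(label = lab, e) else NULL
    }))
  utils::write.table(cat_enr, file.path(outdir, "category_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  accounting <- report_accounting(assignments)
  manifest <- list(
    package_version = as.character(utils::packageVersion("cremap")),
    rng_seed = config$rng_seed,
    parameters = list(alpha = alpha, lfc_threshold = lfc_threshold,
                      cast_threshold = cast_threshold, mode = mode,
                      promoter_length = config$promoter_length,
                      n_genes = config$n_genes),
    records = list(arrays = length(sim$arrays),
                   transcripts_tested = length(unique(results$transcript_id)),
                   regulated = length(sel$genes),
                   clusters = as.list(accounting$counts))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(sim = sim, ratios = ratios, results = results,
                 selection = sel, assignments = assignments,
                 promoters = prom, site_counts = counts,
                 motif_enrichment = enr, annotations = ann,
                 category_enrichment = cat_enr,
                 accounting = accounting, manifest = manifest))
}

#' Load a pipeline configuration from YAML
#'
#' The YAML file holds a `simulate:` mapping of [demo_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y$simulate))
    stop("config file ", path, " lacks a 'simulate:' section",
         call. = FALSE)
  args <- y$simulate
  if (!is.null(args$cluster_sizes))
    args$cluster_sizes <- unlist(args$cluster_sizes)
  do.call(demo_config, args)
}
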
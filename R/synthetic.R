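#' Configuration for a synthetic chemostat array experiment
#'
#' Describes a simulated two-strain, two-growth-rate chemostat design:
#' 4 pairwise comparisons among {wild-type, regulator knockout} x
#' {high dilution rate 0.07 1/h, low dilution rate 0.025 1/h}, each
#' hybridized as 2 dye-swap biological replicates on a multi-probe-per-
#' transcript array.
#'
#' @param n_genes Number of genes on the array.
#' @param probes_per_gene Probes per transcript (default 7).
#' @param true_log2 Either a gene x 4 matrix of true log2 ratios (rownames =
#'   gene ids, one column per comparison) or `NULL` for all-zero truth.
#' @param noise_sd Per-spot Gaussian noise SD in log2-ratio units.
#' @param flag_rate Fraction of spots flagged "not found".
#' @param saturation_rate Fraction of spots driven into scanner saturation.
#' @param promoter_length Promoter length in bases (default 1000).
#' @param background_gc Background GC fraction of promoter sequence
#'   (default 0.5).
#' @param planted_motifs List of planting instructions, each a list with
#'   `motif` (IUPAC string or [dyad_spec()]), `cluster` (target label), and
#'   `rate` (expected planted instances per target-cluster gene).
#' @param cluster_membership Named character vector gene -> label in
#'   {A..H, X, none}; `NULL` assigns "none" everywhere.
#' @param rng_seed Integer seed; identical configs and seeds reproduce
#'   byte-identical outputs.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_genes, probes_per_gene = 7L,
                              true_log2 = NULL, noise_sd = 0.2,
                              flag_rate = 0.02, saturation_rate = 0.01,
                              promoter_length = 1000L, background_gc = 0.5,
                              planted_motifs = list(),
                              cluster_membership = NULL, rng_seed = 1L) {
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 1L)
    stop("invalid `n_genes`", call. = FALSE)
  probes_per_gene <- as.integer(probes_per_gene)
  if (is.na(probes_per_gene) || probes_per_gene < 1L)
    stop("invalid `probes_per_gene`", call. = FALSE)
  for (fld in c("flag_rate", "saturation_rate", "background_gc")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("invalid `", fld, "`: must be a fraction in [0, 1]",
           call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("invalid `noise_sd`: must be >= 0", call. = FALSE)
  promoter_length <- as.integer(promoter_length)
  if (is.na(promoter_length) || promoter_length < 1L)
    stop("invalid `promoter_length`", call. = FALSE)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  if (is.null(true_log2)) {
    true_log2 <- matrix(0, n_genes, 4L,
                        dimnames = list(gene_ids, paste0("c", 1:4)))
  } else {
    if (!is.matrix(true_log2) || ncol(true_log2) != 4L ||
        is.null(rownames(true_log2)))
      stop("invalid `true_log2`: need a gene x 4 matrix with rownames",
           call. = FALSE)
    full <- matrix(0, n_genes, 4L,
                   dimnames = list(gene_ids, colnames(true_log2)))
    known <- intersect(rownames(true_log2), gene_ids)
    if (length(known) < nrow(true_log2))
      stop("invalid `true_log2`: unknown gene id(s)", call. = FALSE)
    full[known, ] <- true_log2[known, ]
    true_log2 <- full
  }
  if (is.null(cluster_membership)) {
    cluster_membership <- stats::setNames(rep("none", n_genes), gene_ids)
  } else {
    bad <- setdiff(unique(cluster_membership),
                   c(LETTERS[1:8], "X", "none"))
    if (length(bad))
      stop("invalid `cluster_membership` label(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    full <- stats::setNames(rep("none", n_genes), gene_ids)
    full[intersect(names(cluster_membership), gene_ids)] <-
      cluster_membership[intersect(names(cluster_membership), gene_ids)]
    cluster_membership <- full
  }
  for (pm in planted_motifs) {
    if (!all(c("motif", "cluster", "rate") %in% names(pm)))
      stop("invalid `planted_motifs`: each entry needs motif/cluster/rate",
           call. = FALSE)
    if (motif_span(pm$motif) > promoter_length)
      stop("invalid `planted_motifs`: motif span exceeds promoter_length",
           call. = FALSE)
  }
  structure(list(
    n_genes = n_genes, gene_ids = gene_ids,
    probes_per_gene = probes_per_gene,
    n_comparisons = 4L, dye_swap_replicates = 2L,
    true_log2 = true_log2, noise_sd = noise_sd,
    flag_rate = flag_rate, saturation_rate = saturation_rate,
    promoter_length = promoter_length, background_gc = background_gc,
    planted_motifs = planted_motifs,
    cluster_membership = cluster_membership,
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

#' Simulate the raw two-channel hybridizations
#'
#' Channel intensities follow a log-normal model with a common per-spot
#' abundance effect: `ch1 = 2^(a + M/2)`, `ch2 = 2^(a - M/2)` with
#' `a ~ N(10, 1.5)` and spot log-ratio `M = s * (true + e)`,
#' `e ~ N(0, noise_sd)`, where the dye-orientation sign `s` is +1 for the
#' first replicate and -1 for the second (dye swap: the reported raw ratio
#' changes sign between replicates). A `flag_rate` fraction of spots is
#' flagged "not found" with both channels drawn from a low background
#' distribution (`2^N(6, 0.5)`); a `saturation_rate` fraction is pushed to
#' the scanner ceiling (65535).
#'
#' @param config A [simulation_config()].
#' @return List with `arrays` (named list `c<k>_r<j>` of GPR-like spot
#'   data.frames), `probe_map` (probe -> transcript data.frame),
#'   `orientation` (per-replicate sign, +1/-1), and `truth` (list with
#'   `true_log2`, `regulated_genes` per comparison at |log2| > 2,
#'   `cluster_membership`).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$rng_seed)
  np <- config$n_genes * config$probes_per_gene
  probe_map <- data.frame(
    probe_id = sprintf("p%06d", seq_len(np)),
    transcript_id = rep(config$gene_ids, each = config$probes_per_gene),
    in_coding_on_matching_strand = TRUE,
    stringsAsFactors = FALSE
  )
  orientation <- c(r1 = 1, r2 = -1)
  arrays <- list()
  for (k in seq_len(config$n_comparisons)) {
    true <- rep(config$true_log2[, k], each = config$probes_per_gene)
    for (j in 1:2) {
      s <- orientation[j]
      a <- stats::rnorm(np, mean = 10, sd = 1.5)
      e <- if (config$noise_sd > 0) stats::rnorm(np, 0, config$noise_sd)
           else numeric(np)
      M <- s * (true + e)
      ch1 <- 2^(a + M / 2)
      ch2 <- 2^(a - M / 2)
      flag <- rep("ok", np)
      nf <- stats::runif(np) < config$flag_rate
      flag[nf] <- "not_found"
      low <- 2^stats::rnorm(sum(nf), 6, 0.5)
      ch1[nf] <- low
      ch2[nf] <- 2^stats::rnorm(sum(nf), 6, 0.5)
      sat <- !nf & stats::runif(np) < config$saturation_rate
      ch1[sat] <- 65535
      ch2[sat] <- 65535
      arrays[[sprintf("c%d_r%d", k, j)]] <- data.frame(
        probe_id = probe_map$probe_id,
        transcript_id = probe_map$transcript_id,
        block = 1L,
        row = ((seq_len(np) - 1L) %/% 100L) + 1L,
        col = ((seq_len(np) - 1L) %% 100L) + 1L,
        F635_mean = ch1,
        F532_mean = ch2,
        flag = flag,
        in_coding_on_matching_strand =
          as.integer(probe_map$in_coding_on_matching_strand),
        stringsAsFactors = FALSE
      )
    }
  }
  regulated <- lapply(seq_len(4L), function(k)
    config$gene_ids[abs(config$true_log2[, k]) > 2])
  names(regulated) <- colnames(config$true_log2)
  list(arrays = arrays, probe_map = probe_map,
       orientation = orientation,
       truth = list(true_log2 = config$true_log2,
                    regulated_genes = regulated,
                    cluster_membership = config$cluster_membership))
}

#' Simulate promoter sequences with planted motif instances
#'
#' Background bases are i.i.d. with the configured GC fraction. For each
#' planting instruction, genes of the target cluster receive a Poisson
#' (rate) number of instances of a random realization of the (degenerate)
#' motif at uniformly random non-overlapping positions; for dyads both
#' components plus a random spacer within the allowed range are written.
#' Exact planted counts per gene and pattern are recorded.
#'
#' @param config A [simulation_config()].
#' @param exact_counts If `TRUE`, plant exactly `round(rate)` instances per
#'   target gene instead of Poisson-distributed counts.
#' @return List with `promoters` (named `DNAStringSet`) and
#'   `planted_counts` (gene x pattern integer matrix) and
#'   `planted_positions` (list of per-gene 0-based start positions).
#' @export
simulate_promoters <- function(config, exact_counts = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$rng_seed + 104729L)  # independent stream from the arrays
  L <- config$promoter_length
  g <- config$background_gc
  base_prob <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
  seqs <- vapply(seq_len(config$n_genes), function(i)
    paste(sample(names(base_prob), L, replace = TRUE, prob = base_prob),
          collapse = ""), character(1))
  names(seqs) <- config$gene_ids
  pm_names <- vapply(config$planted_motifs, function(pm) {
    if (inherits(pm$motif, "dyad_spec"))
      paste0(pm$motif$first, "..", pm$motif$second)
    else as.character(pm$motif)
  }, character(1))
  planted <- matrix(0L, config$n_genes, length(config$planted_motifs),
                    dimnames = list(config$gene_ids, pm_names))
  positions <- stats::setNames(vector("list", config$n_genes),
                               config$gene_ids)
  for (j in seq_along(config$planted_motifs)) {
    pm <- config$planted_motifs[[j]]
    targets <- names(config$cluster_membership)[
      config$cluster_membership == pm$cluster]
    for (gene in targets) {
      n_inst <- if (exact_counts) as.integer(round(pm$rate))
                else stats::rpois(1L, pm$rate)
      if (n_inst < 1L) next
      occupied <- positions[[gene]]
      for (rep_i in seq_len(n_inst)) {
        inst <- realize_motif(pm$motif)
        w <- nchar(inst)
        pos <- place_nonoverlapping(L, w, occupied)
        if (is.na(pos)) break  # promoter too crowded; stop planting
        substr(seqs[[gene]], pos + 1L, pos + w) <- inst
        occupied <- rbind(occupied, c(pos, w))
        planted[gene, j] <- planted[gene, j] + 1L
      }
      positions[[gene]] <- occupied
    }
  }
  list(promoters = Biostrings::DNAStringSet(seqs),
       planted_counts = planted, planted_positions = positions)
}

#' Draw one concrete realization of a degenerate motif or dyad
#' @keywords internal
realize_motif <- function(motif) {
  draw <- function(pat) {
    chars <- strsplit(toupper(as.character(pat)), "", fixed = TRUE)[[1L]]
    paste(vapply(chars, function(ch)
      sample(IUPAC_CODES[[ch]], 1L), character(1)), collapse = "")
  }
  if (inherits(motif, "dyad_spec")) {
    gap <- sample.int(motif$max_gap + 1L, 1L) - 1L
    spacer <- if (gap > 0)
      paste(sample(c("A", "C", "G", "T"), gap, replace = TRUE),
            collapse = "") else ""
    paste0(draw(motif$first), spacer, draw(motif$second))
  } else {
    draw(motif)
  }
}

#' Uniform non-overlapping placement of a width-w instance
#' @keywords internal
place_nonoverlapping <- function(L, w, occupied, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    pos <- sample.int(L - w + 1L, 1L) - 1L
    if (is.null(occupied) ||
        all(pos + w <= occupied[, 1L] | pos >= occupied[, 1L] + occupied[, 2L]))
      return(pos)
  }
  NA_integer_
}

#' Simulate a gene-to-category annotation table
#'
#' A configurable fraction of genes carries at least one category. One
#' chosen category is planted at elevated frequency in one cluster; all
#' other assignments are uniform over the category pool.
#'
#' @param config A [simulation_config()].
#' @param n_categories Size of the category pool (default 20).
#' @param annotated_fraction Fraction of genes with >= 1 category
#'   (default 4977/9129, the annotation density of the T. reesei genome).
#' @param enriched_category Category id planted in `enriched_cluster`
#'   (`NULL` for none).
#' @param enriched_cluster Target cluster label.
#' @param enriched_rate Probability that an annotated target-cluster gene
#'   carries the planted category (default 0.8).
#' @return data.frame `gene_id`, `category_id`, `namespace`.
#' @export
simulate_annotations <- function(config, n_categories = 20L,
                                 annotated_fraction = 4977 / 9129,
                                 enriched_category = NULL,
                                 enriched_cluster = "E",
                                 enriched_rate = 0.8) {
  stopifnot(inherits(config, "sim_config"))
  if (annotated_fraction < 0 || annotated_fraction > 1)
    stop("invalid `annotated_fraction`", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$rng_seed + 224737L)
  n_ann <- round(config$n_genes * annotated_fraction)
  annotated <- sort(sample(config$gene_ids, n_ann))
  cats <- sprintf("cat%03d", seq_len(n_categories))
  rows <- data.frame(
    gene_id = annotated,
    category_id = sample(cats, n_ann, replace = TRUE),
    namespace = "funcat",
    stringsAsFactors = FALSE
  )
  if (!is.null(enriched_category)) {
    targets <- intersect(
      names(config$cluster_membership)[
        config$cluster_membership == enriched_cluster],
      annotated)
    hit <- targets[stats::runif(length(targets)) < enriched_rate]
    if (length(hit))
      rows <- rbind(rows, data.frame(gene_id = hit,
                                     category_id = enriched_category,
                                     namespace = "funcat",
                                     stringsAsFactors = FALSE))
  }
  rows <- unique(rows)
  rows[order(rows$gene_id, rows$category_id), , drop = FALSE]
}

#' Behaviour-class centroids of the chemostat design
#'
#' True log2-ratio centroids over the four comparisons (c1: wild-type low
#' vs high growth rate; c2: knockout low vs high growth rate; c3: knockout
#' vs wild-type at high growth rate; c4: knockout vs wild-type at low
#' growth rate) for nine behaviour classes A-H and X.
#'
#' Pearson correlation on centered 4-condition profiles cannot distinguish
#' a purely growth-rate-regulated profile (m, m, 0, 0) from a purely
#' knockout-regulated one (0, 0, m, m) - after centering they are
#' collinear. The planted classes are therefore built on an orthogonal
#' contrast basis (pairwise correlation at most 0.58 in magnitude), so a
#' template-matching recovery of the planted partition is well posed; each
#' class still mixes growth-rate and knockout responses of magnitude `m`.
#'
#' @param magnitude Absolute log2 effect of a regulated condition
#'   (default 3).
#' @return 9 x 4 numeric matrix, rownames A-H, X.
#' @export
behaviour_centroids <- function(magnitude = 3) {
  m <- magnitude
  rbind(
    A = c( m,  m, -m, -m),
    B = c(-m, -m,  m,  m),
    C = c( m, -m,  m, -m),
    D = c(-m,  m, -m,  m),
    E = c( m, -m, -m,  m),
    F = c(-m,  m,  m, -m),
    G = c( m,  m,  m, -m),
    H = c(-m, -m,  m, -m),
    X = c( m, -m,  m,  m)
  )
}

#' Demo configuration with planted clusters and motifs
#'
#' Builds a complete [simulation_config()] emulating the study design at a
#' reduced problem size: `cluster_sizes` genes per behaviour class placed
#' on `behaviour_centroids()` profiles, the remaining genes null, plus a
#' planted binding-site motif in one cluster's promoters.
#'
#' @param n_genes Total genes (default 1000).
#' @param cluster_sizes Named integer vector over A-H, X. Default scales the
#'   study's cluster proportions down to 125 regulated genes.
#' @param magnitude Centroid magnitude (default 3).
#' @param noise_sd Spot noise SD (default 0.2).
#' @param amplitude_range Per-gene multiplicative amplitude drawn uniformly
#'   from this range (biological within-class dispersion; default
#'   0.85-1.3).
#' @param profile_jitter SD of per-gene, per-condition additive scatter
#'   around the scaled centroid (default 0.25 log2 units). Together with
#'   `amplitude_range` this gives within-class template correlations in the
#'   0.95-0.999 range typical of real expression clusters, so the
#'   min-seed-correlation retrieval rule is exercised realistically.
#' @param planted_motif IUPAC motif planted in `motif_cluster` promoters
#'   (default "SYGGRG").
#' @param motif_cluster Target cluster (default "E").
#' @param motif_rate Planted instances per target gene (default 3).
#' @param rng_seed Seed.
#' @return A `sim_config`.
#' @export
demo_config <- function(n_genes = 1000L,
                        cluster_sizes = c(A = 10, B = 12, C = 8, D = 18,
                                          E = 25, F = 18, G = 13, H = 13,
                                          X = 8),
                        magnitude = 3, noise_sd = 0.2,
                        amplitude_range = c(0.85, 1.3),
                        profile_jitter = 0.25,
                        planted_motif = "SYGGRG", motif_cluster = "E",
                        motif_rate = 3, rng_seed = 1L) {
  cents <- behaviour_centroids(magnitude)
  stopifnot(all(names(cluster_sizes) %in% rownames(cents)))
  n_reg <- sum(cluster_sizes)
  if (n_reg > n_genes) stop("more regulated genes than genes", call. = FALSE)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  membership <- rep(names(cluster_sizes), cluster_sizes)
  names(membership) <- gene_ids[seq_len(n_reg)]
  true <- matrix(0, n_genes, 4L,
                 dimnames = list(gene_ids, paste0("c", 1:4)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(rng_seed) + 424243L)
  amp <- stats::runif(n_reg, amplitude_range[1L], amplitude_range[2L])
  true[seq_len(n_reg), ] <- cents[membership, ] * amp +
    stats::rnorm(n_reg * 4L, 0, profile_jitter)
  simulation_config(
    n_genes = n_genes, true_log2 = true, noise_sd = noise_sd,
    cluster_membership = membership,
    planted_motifs = list(list(motif = planted_motif,
                               cluster = motif_cluster,
                               rate = motif_rate)),
    rng_seed = rng_seed
  )
}
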
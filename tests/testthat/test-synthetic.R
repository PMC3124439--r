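test_that("configuration validation names the offending field", {
  expect_error(simulation_config(0), "n_genes")
  expect_error(simulation_config(10, flag_rate = 1.5), "flag_rate")
  expect_error(simulation_config(10, noise_sd = -1), "noise_sd")
  expect_error(simulation_config(10, background_gc = -0.1), "background_gc")
  expect_error(
    simulation_config(10, promoter_length = 5,
                      planted_motifs = list(list(motif = "SYGGRG",
                                                 cluster = "E", rate = 1))),
    "promoter_length")
})

test_that("identical seeds reproduce identical outputs, different seeds differ", {
  cfg <- simulation_config(n_genes = 100L, rng_seed = 1L)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1, s2)
  p1 <- simulate_promoters(cfg)
  p2 <- simulate_promoters(cfg)
  expect_identical(as.character(p1$promoters), as.character(p2$promoters))
  a1 <- simulate_annotations(cfg)
  expect_identical(a1, simulate_annotations(cfg))
  cfg3 <- simulation_config(n_genes = 100L, rng_seed = 2L)
  expect_false(identical(simulate_experiment(cfg3)$arrays, s1$arrays))
  # file-level determinism
  f1 <- tempfile(); f2 <- tempfile()
  write_gpr_table(s1$arrays[[1]], f1)
  write_gpr_table(s2$arrays[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("zero-noise dye-swap pair recovers the true ratio exactly", {
  true <- matrix(0, 5, 4, dimnames = list(sprintf("g%05d", 1:5),
                                          paste0("c", 1:4)))
  true[1, 1] <- 3
  cfg <- simulation_config(n_genes = 5L, true_log2 = true, noise_sd = 0,
                           flag_rate = 0, saturation_rate = 0, rng_seed = 3L)
  sim <- simulate_experiment(cfg)
  for (r in c("c1_r1", "c1_r2")) {
    a <- sim$arrays[[r]]
    raw <- log2(a$F635_mean / a$F532_mean)
    corrected <- sim$orientation[[sub("c1_", "", r)]] * raw
    expect_equal(corrected[a$transcript_id == "g00001"], rep(3, 7))
    expect_equal(corrected[a$transcript_id == "g00002"], rep(0, 7))
  }
})

test_that("flag_rate = 0 leaves no spot flagged and thresholding signals the case", {
  cfg <- simulation_config(n_genes = 50L, flag_rate = 0, rng_seed = 4L)
  sim <- simulate_experiment(cfg)
  expect_true(all(sim$arrays[[1]]$flag == "ok"))
  a <- sim$arrays[[1]]
  a$ch1 <- a$F635_mean; a$ch2 <- a$F532_mean
  a$in_coding_on_matching_strand <- as.logical(a$in_coding_on_matching_strand)
  expect_error(preprocess_array(a), "not found")
})

test_that("flagged spots sit below the unflagged intensity distribution", {
  cfg <- simulation_config(n_genes = 200L, flag_rate = 0.1, rng_seed = 6L)
  a <- simulate_experiment(cfg)$arrays[[1]]
  expect_lt(mean(a$F635_mean[a$flag == "not_found"]),
            quantile(a$F635_mean[a$flag == "ok"], 0.05))
})

test_that("planted motif counts match an independent scan when background is excluded", {
  # all-AT background cannot produce an incidental GC-containing site
  membership <- setNames(rep(c("E", "none"), c(10, 10)),
                         sprintf("g%05d", 1:20))
  cfg <- simulation_config(
    n_genes = 20L, background_gc = 0, promoter_length = 400L,
    cluster_membership = membership,
    planted_motifs = list(list(motif = "SYGGRG", cluster = "E", rate = 2)),
    rng_seed = 7L)
  prom <- simulate_promoters(cfg, exact_counts = TRUE)
  seqs <- as.character(prom$promoters)
  for (g in names(seqs)) {
    n_scan <- length(oracle_greedy_matches("SYGGRG", seqs[[g]]))
    expect_equal(n_scan, unname(prom$planted_counts[g, 1]))
  }
  expect_true(all(prom$planted_counts[membership == "E", 1] == 2))
  expect_true(all(prom$planted_counts[membership == "none", 1] == 0))
})

test_that("planted instances are recorded at their planted coordinates", {
  membership <- setNames(rep("E", 5), sprintf("g%05d", 1:5))
  cfg <- simulation_config(
    n_genes = 5L, background_gc = 0.5, promoter_length = 500L,
    cluster_membership = membership,
    planted_motifs = list(list(motif = "GTGGAG", cluster = "E", rate = 2)),
    rng_seed = 8L)
  prom <- simulate_promoters(cfg, exact_counts = TRUE)
  for (g in names(prom$planted_positions)) {
    occ <- prom$planted_positions[[g]]
    if (is.null(occ)) next
    s <- as.character(prom$promoters[[g]])
    for (r in seq_len(nrow(occ))) {
      expect_equal(substr(s, occ[r, 1] + 1, occ[r, 1] + occ[r, 2]),
                   "GTGGAG")
    }
  }
})

test_that("scanner counts on unplanted promoters match the i.i.d. background expectation", {
  cfg <- simulation_config(n_genes = 300L, background_gc = 0.5,
                           promoter_length = 1000L, rng_seed = 9L)
  prom <- simulate_promoters(cfg)
  counts <- site_count_matrix(list(m = "SYGGRG"), prom$promoters)[, 1]
  # per-position match probability for SYGGRG at GC fraction g: g^4/32
  g <- 0.5
  expected <- (1000 - 6 + 1) * g^4 / 32
  expect_equal(mean(counts), expected, tolerance = 0.15)
})

test_that("dyad planting writes both components within the allowed spacing", {
  membership <- setNames(rep("D", 6), sprintf("g%05d", 1:6))
  cfg <- simulation_config(
    n_genes = 6L, background_gc = 0, promoter_length = 600L,
    cluster_membership = membership,
    planted_motifs = list(list(motif = dyad_spec("GTGGAG", "GTGGAG", 20),
                               cluster = "D", rate = 1)),
    rng_seed = 10L)
  prom <- simulate_promoters(cfg, exact_counts = TRUE)
  d <- dyad_spec("GTGGAG", "GTGGAG", 20)
  for (g in names(prom$promoters)) {
    expect_gte(scan_dyad(d, prom$promoters[[g]]),
               unname(prom$planted_counts[g, 1]))
  }
})

test_that("annotation simulation hits the configured annotated fraction", {
  cfg <- simulation_config(n_genes = 9129L, rng_seed = 11L)
  ann <- simulate_annotations(cfg, annotated_fraction = 4977 / 9129)
  expect_equal(length(unique(ann$gene_id)), 4977L)
  # planted enrichment is detectable
  membership <- setNames(rep(c("E", "none"), c(30, 270)),
                         sprintf("g%05d", 1:300))
  cfg2 <- simulation_config(n_genes = 300L,
                            cluster_membership = membership, rng_seed = 12L)
  ann2 <- simulate_annotations(cfg2, enriched_category = "planted",
                               enriched_cluster = "E", enriched_rate = 1)
  res <- hypergeom_enrich(names(membership)[membership == "E"], ann2)
  expect_equal(res$category[1], "planted")
  expect_lt(res$p[1], 1e-6)
})

test_that("null annotation enrichment p-values are roughly uniform", {
  set.seed(13)
  genes <- sprintf("g%03d", 1:150)
  pvals <- numeric(0)
  for (i in 1:60) {
    ann <- data.frame(gene_id = genes,
                      category_id = sample(sprintf("c%02d", 1:8), 150,
                                           replace = TRUE),
                      stringsAsFactors = FALSE)
    cluster <- sample(genes, 25)
    res <- hypergeom_enrich(cluster, ann)
    pvals <- c(pvals, res$p)
  }
  # discrete conservative test: sub-uniform tail
  expect_lt(mean(pvals < 0.05), 0.08)
  expect_gt(mean(pvals), 0.35)
})
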
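mk_prof <- function(m, ids = sprintf("g%02d", seq_len(nrow(m)))) {
  rownames(m) <- ids
  colnames(m) <- paste0("c", seq_len(ncol(m)))
  m
}

test_that("template extension retrieves exactly the genes above the seed-fixed threshold", {
  # seeds define the template; R* is the minimum seed correlation
  tmpl <- c(3, 1, -1, -3)
  rot <- function(v, eps) v + eps * c(1, -1, 1, -1)  # bends correlation down
  prof <- mk_prof(rbind(
    s1 = tmpl, s2 = rot(tmpl, 0.4),
    near = rot(tmpl, 0.2),        # correlation above the seeds' minimum
    far = rot(tmpl, 1.5),         # below it
    anti = -tmpl,
    flat = c(1, 1, 1, 1)
  ), ids = c("s1", "s2", "near", "far", "anti", "flat"))
  expect_warning(
    res <- extend_by_template(prof, c("s1", "s2"), mode = "absolute"),
    "constant")
  expect_true(all(c("s1", "s2", "near") %in% res$genes))
  expect_false("far" %in% res$genes)
  # sign symmetry: |r| = 1 for the mirrored profile under the absolute rule
  expect_true("anti" %in% res$genes)
  # signed mode rejects the mirrored profile
  signed <- suppressWarnings(
    extend_by_template(prof, c("s1", "s2"), mode = "signed"))
  expect_false("anti" %in% signed$genes)
  # gene identical to the template is always retrieved
  expect_equal(unname(res$cor["s1"]), cor(tmpl, res$template))
})

test_that("threshold sits between constructed correlations of 0.85 and 0.95", {
  # build vectors with prescribed correlations to a base template
  base <- c(2, 1, -1, -2)
  make_at <- function(r) {
    # mix base direction with an orthogonal one to hit correlation r
    orth <- c(1, -1, -1, 1)
    v <- r * base / sqrt(sum(base^2)) + sqrt(1 - r^2) * orth / sqrt(sum(orth^2))
    v
  }
  prof <- mk_prof(rbind(s1 = base, s2 = make_at(0.9),
                        hi = make_at(0.95), lo = make_at(0.85)),
                  ids = c("s1", "s2", "hi", "lo"))
  res <- extend_by_template(prof, c("s1", "s2"), mode = "signed")
  expect_true("hi" %in% res$genes)
  expect_false("lo" %in% res$genes)
})

test_that("CAST recovers anticorrelated blocks and handles degenerate inputs", {
  set.seed(1)
  up <- c(3, 2, -2, -3); dn <- -up
  block <- rbind(
    t(replicate(5, up + rnorm(4, 0, 0.05))),
    t(replicate(5, dn + rnorm(4, 0, 0.05))))
  prof <- mk_prof(block)
  cl <- cast_cluster(prof, affinity_threshold = 0.8)
  expect_length(cl, 2L)
  sizes <- sort(vapply(cl, length, 1L))
  expect_equal(sizes, c(5L, 5L))
  expect_true(setequal(cl[[1]], sprintf("g%02d", 1:5)) ||
                setequal(cl[[1]], sprintf("g%02d", 6:10)))
  # single gene: one singleton cluster
  expect_equal(cast_cluster(prof[1, , drop = FALSE]), list("g01"))
  # identical genes: one cluster with everything
  same <- mk_prof(matrix(rep(c(1, 2, 3, 4), each = 6), 6, 4))
  expect_length(cast_cluster(same), 1L)
})

test_that("CAST partition is invariant to input row order", {
  set.seed(2)
  prof <- mk_prof(rbind(
    t(replicate(4, c(3, 0, -3, 0) + rnorm(4, 0, 0.1))),
    t(replicate(4, c(0, 3, 0, -3) + rnorm(4, 0, 0.1))),
    t(replicate(3, c(-3, -3, 3, 3) + rnorm(4, 0, 0.1)))))
  canon <- function(cl) sort(vapply(cl, function(g) paste(sort(g), collapse = ","), ""))
  ref <- canon(cast_cluster(prof))
  for (i in 1:5) {
    perm <- sample(nrow(prof))
    expect_equal(canon(cast_cluster(prof[perm, ])), ref)
  }
})

test_that("CAST clusters merge into template groups by the R* rule", {
  tmpl <- c(3, 1, -1, -3)
  # m1/m2 average exactly to the template (correlation 1 >= any R*);
  # o1/o2 have a near-orthogonal mean profile
  prof <- mk_prof(rbind(s1 = tmpl, s2 = tmpl + c(0.2, -0.2, 0.2, -0.2),
                        m1 = tmpl + c(0.3, 0, 0, -0.3),
                        m2 = tmpl - c(0.3, 0, 0, -0.3),
                        o1 = c(1, -1, 1, -1), o2 = c(1, -1.2, 1.1, -1)),
                  ids = c("s1", "s2", "m1", "m2", "o1", "o2"))
  grp <- list(T1 = extend_by_template(prof, c("s1", "s2"), mode = "signed"))
  res <- merge_matching_clusters(list(c("m1", "m2"), c("o1", "o2")),
                                 prof, grp, mode = "signed")
  expect_equal(sort(res$merged$T1), c("m1", "m2"))
  expect_length(res$novel, 1L)
  expect_equal(sort(res$novel[[1]]), c("o1", "o2"))
})

test_that("hierarchical split cuts at the root's two children", {
  # two tight value groups split exactly
  prof <- mk_prof(rbind(matrix(0, 3, 4), matrix(5, 3, 4)))
  halves <- hierarchical_split(prof)
  expect_length(halves, 2L)
  expect_true(setequal(halves[[1]], sprintf("g%02d", 1:3)) ||
                setequal(halves[[1]], sprintf("g%02d", 4:6)))
  # two genes: each its own subcluster
  two <- hierarchical_split(prof[c(1, 4), ])
  expect_equal(lengths(two), c(1L, 1L))
  # singleton: unsplit with warning
  expect_warning(one <- hierarchical_split(prof[1, , drop = FALSE]),
                 "unsplit")
  expect_length(one, 1L)
})

test_that("the cascade partitions all regulated genes over A-H and X", {
  cfg <- demo_config(n_genes = 300L, rng_seed = 5L,
                     cluster_sizes = c(A = 8, B = 8, C = 8, D = 10, E = 12,
                                       F = 10, G = 8, H = 8, X = 6))
  set.seed(5)
  truth <- cfg$cluster_membership[cfg$cluster_membership != "none"]
  prof <- cfg$true_log2[names(truth), ]
  seeds <- lapply(split(names(truth), truth)[LETTERS[1:8]], head, 5)
  ass <- assign_clusters(prof, seeds, mode = "signed")
  expect_setequal(ass$gene_id, rownames(prof))
  expect_equal(anyDuplicated(ass$gene_id), 0L)
  expect_true(all(ass$label %in% c(LETTERS[1:8], "X")))
  expect_true(all(ass$stage %in% c("template", "cast", "cast_novel")))
  # sublabels refine the labels
  expect_true(all(startsWith(ass$sublabel, ass$label)))
})

test_that("planted 9-class structure is recovered with high agreement", {
  skip_if_not_installed("mclust")
  cfg <- demo_config(n_genes = 400L, rng_seed = 8L)
  set.seed(8)
  truth <- cfg$cluster_membership[cfg$cluster_membership != "none"]
  prof <- cfg$true_log2[names(truth), ]
  # measurement noise at the profile level: spot-level SD 0.3 averaged over
  # 7 probes x 2 dye-swap replicates is 0.3/sqrt(14) ~ 0.08 per condition
  prof <- prof + matrix(rnorm(length(prof), 0, 0.08), nrow(prof))
  seeds <- lapply(split(names(truth), truth)[LETTERS[1:8]], head, 8)
  ass <- assign_clusters(prof, seeds, mode = "signed")
  ari <- mclust::adjustedRandIndex(truth[ass$gene_id], ass$label)
  expect_gte(ari, 0.9)
})

test_that("seed files round-trip", {
  df <- data.frame(label = c("A", "A", "B"), gene_id = c("g1", "g2", "g3"))
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- read_seed_file(path)
  expect_equal(s, list(A = c("g1", "g2"), B = "g3"))
})
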
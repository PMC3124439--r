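make_reps <- function(values_mat, ids = sprintf("t%04d", seq_len(nrow(values_mat)))) {
  lapply(seq_len(ncol(values_mat)), function(j)
    data.frame(transcript_id = ids, log2_ratio = values_mat[, j],
               stringsAsFactors = FALSE))
}

test_that("all-zero replicate ratios give t = 0 and p = 1", {
  set.seed(1)
  m <- matrix(rnorm(400, 0, 0.3), ncol = 2)
  m[1, ] <- 0
  res <- fit_moderated(make_reps(m), orientation = c(1, 1))
  row <- res[res$transcript_id == "t0001", ]
  expect_equal(row$mean_log2, 0)
  expect_equal(row$moderated_t, 0)
  expect_equal(row$p, 1)
})

test_that("d0 = 0 recovers the ordinary one-sample t-test", {
  set.seed(2)
  m <- matrix(rnorm(300, 0, 0.5), ncol = 3)
  res <- fit_moderated(make_reps(m), orientation = c(1, 1, 1), d0 = 0,
                       s02 = 1)
  ord <- apply(m, 1, function(v) unname(t.test(v)$statistic))
  ordp <- apply(m, 1, function(v) t.test(v)$p.value)
  expect_equal(res$moderated_t, ord, tolerance = 1e-10)
  expect_equal(res$p, ordp, tolerance = 1e-10)
})

test_that("d0 = Inf gives the pooled-variance z-like statistic", {
  set.seed(3)
  m <- matrix(rnorm(200, 0, 0.5), ncol = 2)
  res <- fit_moderated(make_reps(m), orientation = c(1, 1), d0 = Inf,
                       s02 = 0.25)
  expect_equal(res$moderated_t, res$mean_log2 / (0.5 / sqrt(2)),
               tolerance = 1e-10)
})

test_that("moderated statistics agree with the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(4)
  # heteroscedastic transcripts so the prior degrees of freedom are finite
  sds <- sqrt(0.16 / rchisq(1000, df = 6) * 6)
  m <- matrix(rnorm(3000, 0, rep(sds, 3)), ncol = 3)
  m[1:50, ] <- m[1:50, ] + 2
  res <- fit_moderated(make_reps(m), orientation = c(1, 1, 1))
  fit <- limma::eBayes(limma::lmFit(m))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 0.05)
  expect_equal(attr(res, "s02"), fit$s2.prior, tolerance = 0.02)
  o <- match(res$transcript_id, sprintf("t%04d", seq_len(nrow(m))))
  expect_equal(res$moderated_t, fit$t[o, 1], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(res$p, fit$p.value[o, 1], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("moderated-t type-I error is near nominal under the null", {
  set.seed(5)
  m <- matrix(rnorm(4000, 0, 0.5), ncol = 2)   # 2000 null transcripts
  res <- fit_moderated(make_reps(m), orientation = c(1, 1))
  rate <- mean(res$p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("dye-swap orientation correction recovers the true sign", {
  ids <- c("up", "dn")
  r1 <- data.frame(transcript_id = ids, log2_ratio = c(3.0, -2.5))
  r2 <- data.frame(transcript_id = ids, log2_ratio = c(-3.1, 2.4))
  res <- fit_moderated(list(r1, r2), orientation = c(1, -1))
  expect_equal(res$mean_log2[res$transcript_id == "up"], 3.05)
  expect_equal(res$mean_log2[res$transcript_id == "dn"], -2.45)
})

test_that("transcripts in a single replicate are excluded with a warning", {
  r1 <- data.frame(transcript_id = c("a", "b", "c", "d"),
                   log2_ratio = c(1, 2, 3, 4))
  r2 <- data.frame(transcript_id = c("a", "b", "c"),
                   log2_ratio = c(1.2, 1.7, 3.4))
  expect_warning(res <- fit_moderated(list(r1, r2), orientation = c(1, 1)),
                 "fewer than 2")
  expect_false("d" %in% res$transcript_id)
})

test_that("BH adjustment equals the step-up definition on enumerated cases", {
  cases <- list(
    c(0.01, 0.02, 0.03),
    c(0.5),
    c(0.04, 0.04, 0.04, 0.9),         # ties share the common value
    runif(10),
    c(0.001, 0.9, 0.9, 0.9, 0.0001),
    sort(runif(8), decreasing = TRUE)
  )
  set.seed(6)
  for (p in cases) {
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    expect_true(all(bh_adjust(p) >= p - 1e-15))
    expect_equal(order(bh_adjust(p)[order(p)]), seq_along(p))
  }
})

test_that("selection requires both significance and magnitude", {
  res <- data.frame(
    transcript_id = c("sig_small", "big_nonsig", "both", "both"),
    comparison_id = c("c1", "c1", "c1", "c2"),
    mean_log2 = c(1.5, 3, 2.5, 0.1),
    p_adj = c(0.01, 0.2, 0.01, 0.9),
    stringsAsFactors = FALSE)
  sel <- select_regulated(res)
  expect_equal(sel$genes, "both")
  expect_equal(dim(sel$profiles), c(1L, 2L))
  expect_equal(sel$profiles["both", "c1"], 2.5)
  # the joint criterion is met in c1 only
  expect_true(sel$calls["both", "c1"])
  expect_false(sel$calls["both", "c2"])
})

test_that("selection is monotone in the magnitude threshold and supports exclusion", {
  set.seed(7)
  res <- data.frame(
    transcript_id = sprintf("t%03d", 1:100),
    comparison_id = "c1",
    mean_log2 = rnorm(100, 0, 2),
    p_adj = runif(100, 0, 0.1),
    stringsAsFactors = FALSE)
  hi <- select_regulated(res, lfc_threshold = 2)$genes
  lo <- select_regulated(res, lfc_threshold = 1)$genes
  expect_true(all(hi %in% lo))
  ex <- select_regulated(res, lfc_threshold = 1, exclude = hi)$genes
  expect_false(any(hi %in% ex))
})

test_that("planted regulated genes are recovered with no false positives", {
  cfg <- simulation_config(
    n_genes = 1000L, noise_sd = 0.2,
    true_log2 = {
      m <- matrix(0, 30, 4,
                  dimnames = list(sprintf("g%05d", 1:30), paste0("c", 1:4)))
      m[, 1] <- rep(c(3, -3), 15)
      m
    },
    rng_seed = 11L)
  sim <- simulate_experiment(cfg)
  ratios <- lapply(sim$arrays[c("c1_r1", "c1_r2")], function(a) {
    a$ch1 <- a$F635_mean; a$ch2 <- a$F532_mean
    a$in_coding_on_matching_strand <-
      as.logical(a$in_coding_on_matching_strand)
    preprocess_array(a)$ratios
  })
  res <- fit_moderated(ratios, orientation = sim$orientation,
                       comparison_id = "c1")
  hit <- res$transcript_id[res$p_adj < 0.05 & abs(res$mean_log2) > 2]
  planted <- sprintf("g%05d", 1:30)
  expect_gte(length(intersect(hit, planted)), 28)
  expect_equal(length(setdiff(hit, planted)), 0L)
})
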
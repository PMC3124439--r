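#' Invert the trigamma function
#'
#' Newton iteration on 1/psi'(x), used when matching moments of the scaled-F
#' distribution of residual variances.
#'
#' @param x Positive values of trigamma(y).
#' @return y with trigamma(y) = x (Inf where x <= 0).
#' @keywords internal
trigamma_inverse <- function(x) {
  out <- rep(NA_real_, length(x))
  out[x <= 0] <- Inf
  todo <- which(is.finite(x) & x > 0)
  if (!length(todo)) return(out)
  y <- 0.5 + 1 / x[todo]
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x[todo]) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-8) break
  }
  out[todo] <- y
  out
}

#' Estimate the variance prior by moment matching
#'
#' Fits the scaled inverse chi-square prior (d0, s0^2) for per-transcript
#' residual variances s^2 on d degrees of freedom, by matching the mean and
#' variance of log s^2 (whose excess spread over trigamma(d/2) identifies
#' d0 via trigamma inversion).
#'
#' @param s2 Per-transcript sample variances (zeros excluded from fitting).
#' @param df Residual degrees of freedom (scalar or vector).
#' @return List with `d0` (possibly `Inf`) and `s02`.
#' @export
fit_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  use <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(use) < 2L)
    stop("need at least two positive variances to fit the prior",
         call. = FALSE)
  z <- log(s2[use])
  e <- z - digamma(df[use] / 2) + log(df[use] / 2)
  ebar <- mean(e)
  n <- length(e)
  excess <- mean((e - ebar)^2 * n / (n - 1) - trigamma(df[use] / 2))
  if (excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread over sampling noise: point-mass prior, for which the
    # arithmetic mean of the variances is the natural scale estimate
    d0 <- Inf
    s02 <- mean(s2[use])
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated one-sample t-tests across replicates
#'
#' For each transcript and comparison: the replicate mean and residual
#' variance are computed by ordinary least squares; variances are shrunk
#' toward a prior fitted across transcripts by moment matching
#' ([fit_variance_prior()]); the moderated t statistic
#' `mean / (s_tilde / sqrt(n))` is referred to a t distribution with
#' `d0 + d` degrees of freedom.
#'
#' @param ratios Named list (one element per replicate) of data.frames with
#'   `transcript_id` and `log2_ratio`, already pretreated.
#' @param orientation Numeric vector of +1/-1 per replicate: the sign that
#'   maps each replicate's raw ratio onto the comparison's reference
#'   orientation (dye-swap correction).
#' @param comparison_id Label recorded in the output.
#' @param d0,s02 Optional prior overrides (e.g. `d0 = 0` recovers the
#'   ordinary t-test).
#' @return data.frame with `transcript_id`, `comparison_id`, `mean_log2`,
#'   `s2`, `df_residual`, `moderated_t`, `df_total`, `p`, `p_adj` (BH), and
#'   attributes `d0`, `s02`. Transcripts measured in fewer than two
#'   replicates are excluded with a warning.
#' @export
fit_moderated <- function(ratios, orientation, comparison_id = "c1",
                          d0 = NULL, s02 = NULL) {
  if (length(ratios) != length(orientation))
    stop("one orientation sign per replicate is required", call. = FALSE)
  if (!all(orientation %in% c(-1, 1)))
    stop("orientation must be +1 or -1", call. = FALSE)
  if (length(ratios) < 2L)
    stop("at least two replicates are required", call. = FALSE)
  long <- do.call(rbind, lapply(seq_along(ratios), function(i) {
    r <- ratios[[i]]
    data.frame(transcript_id = r$transcript_id,
               value = orientation[i] * r$log2_ratio,
               stringsAsFactors = FALSE)
  }))
  n <- tapply(long$value, long$transcript_id, length)
  drop <- names(n)[n < 2L]
  if (length(drop))
    warning(length(drop), " transcript(s) present in fewer than 2 ",
            "replicates excluded", call. = FALSE)
  long <- long[!(long$transcript_id %in% drop), , drop = FALSE]
  if (!nrow(long))
    stop("no transcript measured in >= 2 replicates", call. = FALSE)
  n <- tapply(long$value, long$transcript_id, length)
  mn <- tapply(long$value, long$transcript_id, mean)
  s2 <- tapply(long$value, long$transcript_id, stats::var)
  d <- as.numeric(n) - 1
  if (is.null(d0) || is.null(s02)) {
    prior <- fit_variance_prior(as.numeric(s2), d)
    if (is.null(d0)) d0 <- prior$d0
    if (is.null(s02)) s02 <- prior$s02
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * as.numeric(s2)) / (d0 + d)
  se <- sqrt(s2_post / as.numeric(n))
  tt <- ifelse(as.numeric(mn) == 0, 0, as.numeric(mn) / se)
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(tt), df = df_total)
  out <- data.frame(
    transcript_id = names(mn),
    comparison_id = comparison_id,
    mean_log2 = as.numeric(mn),
    s2 = as.numeric(s2),
    df_residual = d,
    moderated_t = tt,
    df_total = df_total,
    p = p,
    p_adj = bh_adjust(p),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; ties receive the common adjusted value.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Select regulated transcripts and build the 4-condition profile matrix
#'
#' A transcript is called regulated when, in at least one comparison, its BH
#' adjusted p-value is below `alpha` and |mean log2 ratio| exceeds
#' `lfc_threshold` (the strict "> 2 or < -2" magnitude rule).
#'
#' @param results data.frame rbind-ed over comparisons as produced by
#'   [fit_moderated()] (needs `transcript_id`, `comparison_id`, `mean_log2`,
#'   `p_adj`).
#' @param alpha Adjusted p-value cutoff (default 0.05).
#' @param lfc_threshold Absolute log2 ratio that must be exceeded
#'   (default 2).
#' @param exclude Transcript ids removed from the result (e.g. the deleted
#'   regulator gene itself, whose apparent regulation is trivial).
#' @return List with `genes` (character vector), `profiles` (gene x
#'   comparison matrix of mean log2 ratios), and `calls` (logical matrix of
#'   per-comparison regulation calls).
#' @export
select_regulated <- function(results, alpha = 0.05, lfc_threshold = 2,
                             exclude = character(0)) {
  results <- results[!(results$transcript_id %in% exclude), , drop = FALSE]
  hit <- results$p_adj < alpha & abs(results$mean_log2) > lfc_threshold
  genes <- sort(unique(results$transcript_id[hit]))
  comps <- sort(unique(results$comparison_id))
  profiles <- matrix(NA_real_, length(genes), length(comps),
                     dimnames = list(genes, comps))
  calls <- matrix(FALSE, length(genes), length(comps),
                  dimnames = list(genes, comps))
  sub <- results[results$transcript_id %in% genes, , drop = FALSE]
  idx <- cbind(match(sub$transcript_id, genes),
               match(sub$comparison_id, comps))
  profiles[idx] <- sub$mean_log2
  calls[idx] <- sub$p_adj < alpha & abs(sub$mean_log2) > lfc_threshold
  # a gene discarded by the detectability rules in one comparison carries no
  # change evidence there: profile entry set to 0 so profiles stay finite
  profiles[is.na(profiles)] <- 0
  list(genes = genes, profiles = profiles, calls = calls)
}
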
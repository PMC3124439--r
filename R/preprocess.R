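#' Background threshold from "not found" features
#'
#' Features the gridding software could not locate carry only background
#' signal; the detectability threshold is their mean intensity plus two
#' sample standard deviations (n-1 denominator). The standard deviation of a
#' single value is taken as 0.
#'
#' @param not_found_intensities Numeric vector of intensities from spots
#'   flagged "not found" (per-channel means, pooled across channels).
#' @return The threshold (mean + 2 SD).
#' @examples
#' compute_background_threshold(c(90, 100, 110))  # 120
#' @export
compute_background_threshold <- function(not_found_intensities) {
  x <- not_found_intensities
  if (length(x) == 0L)
    stop("no 'not found' features: background threshold undefined",
         call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("intensities must be finite and nonnegative", call. = FALSE)
  s <- if (length(x) == 1L) 0 else stats::sd(x)
  mean(x) + 2 * s
}

#' Global intensity-dependent (lowess) normalization
#'
#' Fits a locally weighted regression of M = log2(ch1/ch2) on
#' A = 0.5 * log2(ch1 * ch2) over all retained spots and returns the
#' residuals M - trend(A). No background subtraction is performed at any
#' point. Flagged and saturating spots must already have been discarded.
#'
#' @param ch1,ch2 Positive channel intensities of the retained spots.
#' @param span Lowess span (fraction of points in the local window).
#' @param iterations Robustness iterations of the symmetric (Tukey biweight)
#'   family.
#' @return List with `M` (normalized log-ratios), `A`, and `trend` (the
#'   fitted values removed).
#' @export
normalize_global <- function(ch1, ch2, span = 0.3, iterations = 3L) {
  if (length(ch1) != length(ch2))
    stop("channel vectors differ in length", call. = FALSE)
  if (any(ch1 <= 0) || any(ch2 <= 0))
    stop("channel intensities must be positive for ratio normalization",
         call. = FALSE)
  M <- log2(ch1) - log2(ch2)
  A <- 0.5 * (log2(ch1) + log2(ch2))
  if (length(M) < 10L)
    stop("too few spots (", length(M), ") for lowess normalization",
         call. = FALSE)
  if (stats::var(M) == 0) {
    # flat ratio surface: the trend is the constant itself
    return(list(M = M - M[1L], A = A, trend = rep(M[1L], length(M))))
  }
  fit <- stats::loess(M ~ A, span = span, degree = 1,
                      family = "symmetric",
                      control = stats::loess.control(iterations = iterations,
                                                     surface = "direct"))
  trend <- stats::predict(fit, A)
  list(M = M - trend, A = A, trend = trend)
}

#' Pretreat one hybridization result table
#'
#' Applies the full per-array pretreatment: (1) compute the background
#' threshold from "not found" features; (2) discard flagged and saturating
#' spots; (3) lowess-normalize the survivors; (4) call detectability (raw
#' intensities above background); (5) average normalized log2 ratios over
#' detectable probes lying in the coding sequence on the matching strand,
#' discarding transcripts with fewer than two such probes.
#'
#' @param spots data.frame with columns `probe_id`, `transcript_id`,
#'   `in_coding_on_matching_strand` (logical), `ch1`, `ch2`, `flag`
#'   (`"ok"`, `"not_found"`, `"other_bad"`), as written/read by
#'   [read_gpr_table()].
#' @param saturation Scanner ceiling; spots with either channel at or above
#'   it are discarded as saturating. Default `2^16 - 1`.
#' @param detect_channels `"both"` (default): a spot is detectable when both
#'   raw channel means exceed the background threshold; `"either"`: one
#'   suffices.
#' @param span,iterations Passed to [normalize_global()].
#' @return List with `ratios` (data.frame `transcript_id`, `log2_ratio`,
#'   `n_probes`), `background_threshold`, and `probes` (per-probe normalized
#'   M with detectability calls).
#' @export
preprocess_array <- function(spots, saturation = 2^16 - 1,
                             detect_channels = c("both", "either"),
                             span = 0.3, iterations = 3L) {
  detect_channels <- match.arg(detect_channels)
  req <- c("probe_id", "transcript_id", "in_coding_on_matching_strand",
           "ch1", "ch2", "flag")
  miss <- setdiff(req, names(spots))
  if (length(miss))
    stop("spot table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  nf <- spots$flag == "not_found"
  bg <- compute_background_threshold(c(spots$ch1[nf], spots$ch2[nf]))
  keep <- spots$flag == "ok" &
    spots$ch1 < saturation & spots$ch2 < saturation &
    spots$ch1 > 0 & spots$ch2 > 0
  retained <- spots[keep, , drop = FALSE]
  nrm <- normalize_global(retained$ch1, retained$ch2,
                          span = span, iterations = iterations)
  detectable <- if (detect_channels == "both")
    retained$ch1 > bg & retained$ch2 > bg
  else
    retained$ch1 > bg | retained$ch2 > bg
  probes <- data.frame(
    probe_id = retained$probe_id,
    transcript_id = retained$transcript_id,
    in_coding_on_matching_strand = retained$in_coding_on_matching_strand,
    M = nrm$M, A = nrm$A,
    detectable = detectable,
    stringsAsFactors = FALSE
  )
  ratios <- aggregate_transcripts(probes)
  list(ratios = ratios, background_threshold = bg, probes = probes)
}

#' Average probe log-ratios into transcript ratios
#'
#' Unweighted mean of normalized M over probes that are detectable and lie
#' inside the coding sequence on the matching strand; transcripts with fewer
#' than two qualifying probes are discarded.
#'
#' @param probes data.frame with `transcript_id`,
#'   `in_coding_on_matching_strand`, `M`, `detectable` (see
#'   [preprocess_array()]). Probes with missing transcript assignment are
#'   ignored.
#' @param min_probes Minimum qualifying probes per transcript (default 2).
#' @return data.frame `transcript_id`, `log2_ratio`, `n_probes`.
#' @export
aggregate_transcripts <- function(probes, min_probes = 2L) {
  ok <- probes$detectable & probes$in_coding_on_matching_strand &
    !is.na(probes$transcript_id) & probes$transcript_id != ""
  q <- probes[ok, , drop = FALSE]
  if (!nrow(q))
    return(data.frame(transcript_id = character(0), log2_ratio = numeric(0),
                      n_probes = integer(0), stringsAsFactors = FALSE))
  m <- tapply(q$M, q$transcript_id, mean)
  n <- tapply(q$M, q$transcript_id, length)
  out <- data.frame(transcript_id = names(m),
                    log2_ratio = as.numeric(m),
                    n_probes = as.integer(n),
                    stringsAsFactors = FALSE)
  out <- out[out$n_probes >= min_probes, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$transcript_id), , drop = FALSE]
}

#' Read / write GPR-like spot tables
#'
#' The pipeline's raw-array interchange format is a TSV with columns
#' `probe_id`, `transcript_id`, `block`, `row`, `col`, `F635_mean`
#' (channel 1), `F532_mean` (channel 2), `flag`
#' (`ok` / `not_found` / `other_bad`), and
#' `in_coding_on_matching_strand` (0/1).
#'
#' @param path File path.
#' @return For `read_gpr_table`, a data.frame with normalized column names
#'   `ch1`/`ch2` as expected by [preprocess_array()].
#' @export
read_gpr_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("probe_id", "transcript_id", "F635_mean", "F532_mean", "flag",
           "in_coding_on_matching_strand")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("array table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$ch1 <- as.numeric(df$F635_mean)
  df$ch2 <- as.numeric(df$F532_mean)
  df$in_coding_on_matching_strand <-
    as.logical(as.integer(df$in_coding_on_matching_strand))
  df
}

#' @rdname read_gpr_table
#' @param spots data.frame in the layout produced by [simulate_experiment()].
#' @export
write_gpr_table <- function(spots, path) {
  utils::write.table(spots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
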
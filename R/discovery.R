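#' Per-promoter presence counts of all words of a given length
#'
#' @param promoters `DNAStringSet` (or named character vector).
#' @param width Word length.
#' @param chunk Sequences per chunk (bounds the transient count matrix).
#' @return Named integer vector: for every word, the number of promoters
#'   containing it at least once.
#' @keywords internal
word_presence_counts <- function(promoters, width, chunk = 200L) {
  promoters <- as_promoter_set(promoters)
  total <- NULL
  for (i in seq(1L, length(promoters), by = chunk)) {
    idx <- i:min(i + chunk - 1L, length(promoters))
    f <- Biostrings::oligonucleotideFrequency(promoters[idx], width = width)
    pres <- colSums(f > 0L)
    total <- if (is.null(total)) pres else total + pres
  }
  total
}

#' De novo discovery of over-represented words with random controls
#'
#' For every exact word of the requested lengths, the occurrence
#' (presence/absence per promoter) in the cluster is scored as
#' `-log10` of the binomial upper-tail p-value given the word's per-promoter
#' occurrence probability estimated from the genome promoter set (with a
#' Laplace-style pseudocount so unseen words keep a finite score). In
#' parallel, `n_controls` random gene groups of the same size are scored the
#' same way; only words whose score exceeds the highest control score (for
#' that word length) plus `margin` are accepted.
#'
#' @param cluster_genes Character vector of gene ids (nonempty, subset of
#'   the promoter set names).
#' @param promoters Named `DNAStringSet` of all genome promoters (the
#'   background universe).
#' @param word_lengths Integer vector of word lengths (default 5:8).
#' @param n_controls Number of random same-size control groups (default 3).
#' @param margin Score margin over the best control (default 0.5).
#' @param seed Integer seed for drawing the control groups.
#' @param min_presence Minimum cluster promoters containing a word for it to
#'   be scored (default 2; suppresses singleton noise).
#' @return data.frame of accepted words: `word`, `width`, `k` (cluster
#'   promoters containing it), `n` (cluster size), `expected_prob`, `score`,
#'   `control_max`, sorted by decreasing score. Attribute `thresholds` gives
#'   the per-length acceptance thresholds.
#' @export
discover_motifs <- function(cluster_genes, promoters, word_lengths = 5:8,
                            n_controls = 3L, margin = 0.5, seed = 1L,
                            min_presence = 2L) {
  promoters <- as_promoter_set(promoters)
  cluster_genes <- as.character(cluster_genes)
  if (!length(cluster_genes)) stop("cluster is empty", call. = FALSE)
  miss <- setdiff(cluster_genes, names(promoters))
  if (length(miss))
    stop("cluster gene(s) without promoter: ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- length(cluster_genes)
  if (n > length(promoters))
    stop("cluster larger than promoter universe", call. = FALSE)
  N <- length(promoters)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  controls <- lapply(seq_len(n_controls), function(i)
    sample(names(promoters), n))
  accepted <- list()
  thresholds <- numeric(0)
  for (w in word_lengths) {
    bgk <- word_presence_counts(promoters, w)
    prob <- (bgk + 0.5) / (N + 1)
    score_set <- function(genes) {
      k <- word_presence_counts(promoters[genes], w)
      s <- -stats::pbinom(k - 1L, n, prob, lower.tail = FALSE,
                          log.p = TRUE) / log(10)
      s[k < min_presence] <- 0
      list(k = k, score = s)
    }
    obs <- score_set(cluster_genes)
    ctl_max <- max(vapply(controls, function(g) max(score_set(g)$score),
                          numeric(1)))
    thr <- ctl_max + margin
    thresholds[as.character(w)] <- thr
    hit <- which(obs$score > thr)
    if (length(hit)) {
      accepted[[length(accepted) + 1L]] <- data.frame(
        word = names(obs$k)[hit], width = w,
        k = as.integer(obs$k[hit]), n = n,
        expected_prob = unname(prob[hit]),
        score = unname(obs$score[hit]), control_max = ctl_max,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(accepted)) do.call(rbind, accepted) else
    data.frame(word = character(0), width = integer(0), k = integer(0),
               n = integer(0), expected_prob = numeric(0),
               score = numeric(0), control_max = numeric(0),
               stringsAsFactors = FALSE)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "thresholds") <- thresholds
  out
}

#' De novo discovery of spaced trinucleotide dyads
#'
#' Same control-based acceptance rule as [discover_motifs()], applied to
#' ordered pairs of trinucleotides separated by a fixed spacer in a bounded
#' range (presence/absence per promoter).
#'
#' @inheritParams discover_motifs
#' @param spacers Integer vector of spacer lengths considered (default
#'   0:20).
#' @return data.frame of accepted dyads: `first`, `second`, `spacer`, `k`,
#'   `n`, `expected_prob`, `score`, `control_max`.
#' @export
discover_dyads <- function(cluster_genes, promoters, spacers = 0:20,
                           n_controls = 3L, margin = 0.5, seed = 1L,
                           min_presence = 2L) {
  promoters <- as_promoter_set(promoters)
  cluster_genes <- as.character(cluster_genes)
  if (!length(cluster_genes)) stop("cluster is empty", call. = FALSE)
  n <- length(cluster_genes)
  N <- length(promoters)
  if (n > N) stop("cluster larger than promoter universe", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  controls <- lapply(seq_len(n_controls), function(i)
    sample(names(promoters), n))
  bg <- dyad_presence_counts(promoters, spacers)
  prob <- (bg + 0.5) / (N + 1)
  score_set <- function(genes) {
    kr <- dyad_presence_counts(promoters[genes], spacers)
    # genes are a subset of the universe, so every observed key is in `prob`
    k <- stats::setNames(integer(length(prob)), names(prob))
    k[names(kr)] <- kr
    s <- -stats::pbinom(k - 1L, n, prob, lower.tail = FALSE,
                        log.p = TRUE) / log(10)
    s[k < min_presence] <- 0
    list(k = k, score = s)
  }
  obs <- score_set(cluster_genes)
  ctl_max <- max(vapply(controls, function(g) max(score_set(g)$score),
                        numeric(1)))
  thr <- ctl_max + margin
  hit <- which(obs$score > thr)
  ids <- names(obs$k)[hit]
  parts <- strsplit(ids, "|", fixed = TRUE)
  out <- data.frame(
    first = vapply(parts, `[`, "", 1L),
    second = vapply(parts, `[`, "", 3L),
    spacer = as.integer(vapply(parts, `[`, "", 2L)),
    k = as.integer(obs$k[hit]), n = n,
    expected_prob = unname(prob[hit]),
    score = unname(obs$score[hit]), control_max = ctl_max,
    stringsAsFactors = FALSE)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Per-promoter presence counts of spaced trinucleotide pairs
#' @keywords internal
dyad_presence_counts <- function(promoters, spacers) {
  promoters <- as_promoter_set(promoters)
  tri <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 3L)
  counts <- new.env(parent = emptyenv())
  for (i in seq_along(promoters)) {
    s <- as.character(promoters[[i]])
    L <- nchar(s)
    if (L < 6L) next
    starts <- seq_len(L - 2L)
    words <- substring(s, starts, starts + 2L)
    id <- match(words, tri)           # NA for windows containing N
    seen <- character(0)
    for (d in spacers) {
      off <- 3L + d
      if (length(id) <= off) next
      a <- id[seq_len(length(id) - off)]
      b <- id[(off + 1L):length(id)]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) next
      keys <- paste0(tri[a[ok]], "|", d, "|", tri[b[ok]])
      seen <- c(seen, unique(keys))
    }
    for (k in unique(seen)) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  keys <- ls(counts)
  stats::setNames(vapply(keys, function(k) counts[[k]], integer(1)), keys)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}
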
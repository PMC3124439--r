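#' Scan a sequence for non-overlapping IUPAC pattern matches
#'
#' Left-to-right greedy matching as performed by classical promoter pattern
#' matchers with overlap prevention on: positions are scanned in increasing
#' order and a match at position `i` consuming `L` bases makes the scan
#' resume at `i + L`. `N` in the sequence matches nothing. Only the given
#' strand is scanned; reverse-strand occurrences are obtained by scanning the
#' explicit reverse-complement pattern (e.g. `CYCCRS` for `SYGGRG`).
#'
#' @param pattern An [iupac_pattern()] or string coercible to one.
#' @param sequence A character scalar, `DNAString`, or single-element
#'   `DNAStringSet` (uppercase A/C/G/T/N).
#' @param overlap If `TRUE`, return all (possibly overlapping) match
#'   positions instead of applying greedy consumption.
#' @return Integer vector of 0-based match start positions.
#' @examples
#' scan_pattern("SYGGRG", "CTGGAGAAA")      # 0
#' scan_pattern("GTGGAG", "GTGGAGGTGGAG")   # 0 6
#' @export
scan_pattern <- function(pattern, sequence, overlap = FALSE) {
  pattern <- iupac_pattern(pattern)
  subject <- as_dna_string(sequence)
  L <- nchar(pattern)
  if (length(subject) < L) return(integer(0))
  hits <- Biostrings::matchPattern(unclass(pattern), subject,
                                   fixed = "subject")
  starts <- BiocGenerics::start(hits)
  if (length(starts)) {
    # unknown bases are unmatchable even under a degenerate (e.g. N) pattern
    windows <- as.character(Biostrings::extractAt(
      subject, IRanges::IRanges(starts, width = L)))
    starts <- starts[!grepl("N", windows, fixed = TRUE)]
  }
  starts <- sort(starts)
  if (!overlap && length(starts) > 1L) {
    keep <- logical(length(starts))
    next_free <- 1L
    for (i in seq_along(starts)) {
      if (starts[i] >= next_free) {
        keep[i] <- TRUE
        next_free <- starts[i] + L
      }
    }
    starts <- starts[keep]
  }
  as.integer(starts - 1L)
}

as_dna_string <- function(sequence) {
  if (inherits(sequence, "DNAString")) return(sequence)
  if (inherits(sequence, "DNAStringSet")) {
    if (length(sequence) != 1L)
      stop("expected a single sequence", call. = FALSE)
    return(sequence[[1L]])
  }
  Biostrings::DNAString(toupper(as.character(sequence)))
}

#' Count dyad (paired motif) occurrences in a sequence
#'
#' Match positions for the two component motifs are produced independently by
#' [scan_pattern()]; every ordered pair (i, j) with the second motif starting
#' at or after the end of the first and a gap within the allowed range counts
#' once.
#'
#' @param dyad A [dyad_spec()].
#' @param sequence As in [scan_pattern()].
#' @param anchor `"end_start"` (default): gap measured from the end of the
#'   first motif to the start of the second, overlapping components excluded.
#'   `"start_start"`: spacing measured start-to-start (components may then
#'   overlap if `max_gap` < length of first).
#' @param overlap Passed to [scan_pattern()] for the component scans.
#' @return Integer pair count.
#' @examples
#' d <- dyad_spec("SYGGRG", "SYGGRG", max_gap = 20)
#' scan_dyad(d, paste0("CTGGAG", strrep("A", 10), "GCGGGG"))
#' @export
scan_dyad <- function(dyad, sequence, anchor = c("end_start", "start_start"),
                      overlap = FALSE) {
  stopifnot(inherits(dyad, "dyad_spec"))
  anchor <- match.arg(anchor)
  subject <- as_dna_string(sequence)
  p1 <- scan_pattern(dyad$first, subject, overlap = overlap)
  p2 <- if (unclass(dyad$first) == unclass(dyad$second)) p1 else
    scan_pattern(dyad$second, subject, overlap = overlap)
  if (!length(p1) || !length(p2)) return(0L)
  L1 <- nchar(dyad$first)
  n <- 0L
  for (i in p1) {
    gap <- if (anchor == "end_start") p2 - (i + L1) else p2 - i
    ok <- if (anchor == "end_start") gap >= 0L & gap <= dyad$max_gap
          else p2 > i & gap <= dyad$max_gap
    n <- n + sum(ok)
  }
  as.integer(n)
}

#' Per-gene site counts for a set of motifs and dyads
#'
#' @param motifs Named list of IUPAC patterns (strings) and/or [dyad_spec()]s.
#' @param promoters Named `DNAStringSet` (or named character vector) of
#'   promoter sequences, one per gene.
#' @param ... Passed on to [scan_pattern()] / [scan_dyad()].
#' @return Integer matrix, genes x motifs.
#' @export
site_count_matrix <- function(motifs, promoters, ...) {
  if (is.null(names(motifs)) || any(names(motifs) == ""))
    stop("`motifs` must be a fully named list", call. = FALSE)
  promoters <- as_promoter_set(promoters)
  out <- matrix(0L, nrow = length(promoters), ncol = length(motifs),
                dimnames = list(names(promoters), names(motifs)))
  for (j in seq_along(motifs)) {
    m <- motifs[[j]]
    for (i in seq_along(promoters)) {
      out[i, j] <- if (inherits(m, "dyad_spec"))
        scan_dyad(m, promoters[[i]], ...)
      else
        length(scan_pattern(m, promoters[[i]], ...))
    }
  }
  out
}

as_promoter_set <- function(promoters) {
  if (inherits(promoters, "DNAStringSet")) {
    if (is.null(names(promoters)))
      stop("promoter set must be named by gene id", call. = FALSE)
    return(promoters)
  }
  if (is.character(promoters)) {
    if (is.null(names(promoters)))
      stop("promoter set must be named by gene id", call. = FALSE)
    return(Biostrings::DNAStringSet(toupper(promoters)))
  }
  stop("unsupported promoter container: ", class(promoters)[1L], call. = FALSE)
}
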
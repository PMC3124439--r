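#' IUPAC degenerate nucleotide codes
#'
#' Named list mapping each IUPAC symbol to the set of unambiguous bases it
#' stands for. `N` in a *sequence* is never matched by any pattern symbol
#' (unknown bases are treated as unmatchable, not as wildcards).
#'
#' @keywords internal
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Construct a validated IUPAC pattern
#'
#' @param pattern Character scalar over the 15 IUPAC nucleotide codes
#'   (case-insensitive).
#' @return A character scalar of class `iupac_pattern` (uppercase).
#' @examples
#' iupac_pattern("SYGGRG")
#' @export
iupac_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern))
    stop("`pattern` must be a single character string", call. = FALSE)
  pattern <- toupper(pattern)
  if (nchar(pattern) == 0L)
    stop("IUPAC pattern must be nonempty", call. = FALSE)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), names(IUPAC_CODES))
  if (length(bad))
    stop("invalid IUPAC character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(pattern, class = "iupac_pattern")
}

#' Reverse complement of an IUPAC pattern
#'
#' The complement of a degenerate symbol is the symbol covering the
#' complements of its base set (e.g. `SYGGRG` -> `CYCCRS`).
#'
#' @param pattern An [iupac_pattern()] or string coercible to one.
#' @return An `iupac_pattern`.
#' @examples
#' reverse_complement_pattern("SYGGRG")  # CYCCRS
#' @export
reverse_complement_pattern <- function(pattern) {
  pattern <- iupac_pattern(pattern)
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  chars <- strsplit(unclass(pattern), "", fixed = TRUE)[[1L]]
  iupac_pattern(paste(rev(unname(comp[chars])), collapse = ""))
}

#' Specify a dyad (ordered motif pair with bounded spacer)
#'
#' A dyad is an occurrence of `first` followed downstream by `second` with a
#' gap (end of first to start of second) between 0 and `max_gap` bases.
#' Dyads proxy the cooperative double binding sites required for direct
#' CreA/CRE1 repression.
#'
#' @param first,second IUPAC patterns.
#' @param max_gap Maximum spacer length in bases (>= 0); the original
#'   analysis used 20 and 50.
#' @return A list of class `dyad_spec`.
#' @export
dyad_spec <- function(first, second, max_gap = 20L) {
  max_gap <- as.integer(max_gap)
  if (is.na(max_gap) || max_gap < 0L)
    stop("`max_gap` must be a nonnegative integer", call. = FALSE)
  structure(
    list(first = iupac_pattern(first), second = iupac_pattern(second),
         max_gap = max_gap),
    class = "dyad_spec"
  )
}

#' @export
print.dyad_spec <- function(x, ...) {
  cat(sprintf("<dyad> %s ... %s (gap 0..%d)\n", x$first, x$second, x$max_gap))
  invisible(x)
}

#' Longest possible span of a motif or dyad
#' @keywords internal
motif_span <- function(x) {
  if (inherits(x, "dyad_spec"))
    nchar(x$first) + x$max_gap + nchar(x$second)
  else
    nchar(unclass(iupac_pattern(x)))
}
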
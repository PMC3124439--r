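# Independent brute-force oracles, deliberately naive and separate from the
# package's implementation paths.

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# all (possibly overlapping) 0-based window matches, by direct window test
oracle_all_matches <- function(pattern, sequence) {
  pat <- strsplit(toupper(pattern), "")[[1]]
  seq <- strsplit(toupper(sequence), "")[[1]]
  L <- length(pat)
  if (length(seq) < L) return(integer(0))
  hits <- integer(0)
  for (i in 0:(length(seq) - L)) {
    win <- seq[(i + 1):(i + L)]
    ok <- all(vapply(seq_len(L), function(j)
      win[j] %in% iupac_sets[[pat[j]]] && win[j] != "N", logical(1)))
    if (ok) hits <- c(hits, i)
  }
  hits
}

# greedy left-to-right non-overlapping consumption of the window matches
oracle_greedy_matches <- function(pattern, sequence) {
  all <- oracle_all_matches(pattern, sequence)
  L <- nchar(pattern)
  out <- integer(0)
  nxt <- 0L
  for (i in all) {
    if (i >= nxt) {
      out <- c(out, i)
      nxt <- i + L
    }
  }
  out
}

# exhaustive ordered-pair enumeration for dyad counting
oracle_dyad_count <- function(first, second, max_gap, sequence,
                              anchor = "end_start") {
  p1 <- oracle_greedy_matches(first, sequence)
  p2 <- oracle_greedy_matches(second, sequence)
  L1 <- nchar(first)
  n <- 0L
  for (i in p1) for (j in p2) {
    g <- if (anchor == "end_start") j - (i + L1) else j - i
    ok <- if (anchor == "end_start") g >= 0 && g <= max_gap
          else j > i && g <= max_gap
    if (ok) n <- n + 1L
  }
  n
}

# step-up BH adjustment written straight from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
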
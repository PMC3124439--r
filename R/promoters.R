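#' Retrieve upstream promoter sequences
#'
#' Extracts the `length` bases immediately upstream of each gene's coding
#' start (positions -length..-1 relative to the start codon): for plus-strand
#' genes the window 5' of `start`, for minus-strand genes the reverse
#' complement of the window 3' of `end`. Windows are truncated (with a
#' warning) at contig edges. Upstream ORFs are not masked or clipped by
#' default.
#'
#' @param genes A data.frame with columns `gene_id`, `seqid`, `start`, `end`
#'   (1-based, inclusive) and `strand` (`"+"`/`"-"`), as read by
#'   [read_gene_table()].
#' @param genome A named `DNAStringSet` (e.g. from
#'   `Biostrings::readDNAStringSet()`).
#' @param length Promoter length in bases (default 1000, i.e. coordinates
#'   -1000 to -1).
#' @return A named `DNAStringSet` of promoters (one per gene; genes whose
#'   window is empty are dropped with a warning).
#' @export
retrieve_promoters <- function(genes, genome, length = 1000L) {
  req <- c("gene_id", "seqid", "start", "end", "strand")
  miss <- setdiff(req, names(genes))
  if (base::length(miss))
    stop("gene table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  length <- as.integer(length)
  if (is.na(length) || length < 1L)
    stop("`length` must be a positive integer", call. = FALSE)
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  bad <- setdiff(unique(genes$seqid), names(genome))
  if (base::length(bad)) {
    g1 <- genes$gene_id[match(bad[1L], genes$seqid)]
    stop("contig '", bad[1L], "' (gene ", g1, ") absent from genome",
         call. = FALSE)
  }
  seqs <- vector("list", nrow(genes))
  truncated <- character(0)
  for (i in seq_len(nrow(genes))) {
    contig <- genome[[genes$seqid[i]]]
    clen <- base::length(contig)
    if (genes$strand[i] == "+") {
      to <- genes$start[i] - 1L
      from <- max(1L, genes$start[i] - length)
      if (to < from) { from <- 1L; to <- 0L }
      s <- if (to >= from) Biostrings::subseq(contig, from, to)
           else Biostrings::DNAString("")
    } else {
      from <- genes$end[i] + 1L
      to <- min(clen, genes$end[i] + length)
      s <- if (to >= from)
        Biostrings::reverseComplement(Biostrings::subseq(contig, from, to))
        else Biostrings::DNAString("")
    }
    if (base::length(s) < length) truncated <- c(truncated, genes$gene_id[i])
    seqs[[i]] <- s
  }
  if (base::length(truncated))
    warning("promoter truncated at contig edge for: ",
            paste(truncated, collapse = ", "), call. = FALSE)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- genes$gene_id
  keep <- Biostrings::width(out) > 0L
  if (any(!keep))
    warning(sum(!keep), " gene(s) with empty promoter window dropped",
            call. = FALSE)
  out[keep]
}

#' Read a GFF-like gene coordinate table
#'
#' A plain TSV with header columns `gene_id`, `seqid`, `start`, `end`,
#' `strand`; coordinates 1-based inclusive.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "seqid", "start", "end", "strand")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("gene table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}
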
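#' Soft-mask over-represented k-mers
#'
#' Counts every k-mer across a set of sequences (forward strand,
#' overlapping occurrences counted, k-mers containing N ignored) and
#' lowercases every base covered by an occurrence of a k-mer seen more
#' than `max_occ` times. Used to mask repetitive probe-flank regions that
#' RepeatMasker misses before read alignment and SNP calling. Sequences
#' shorter than `k` are returned untouched.
#'
#' @param sequences Named character vector of sequences over
#'   \{A,C,G,T,N\} (case-insensitive), or a `Biostrings::DNAStringSet`.
#' @param k K-mer length (default 16).
#' @param max_occ Maximum tolerated occurrence count (default 5);
#'   k-mers occurring more than this are masked.
#' @return A list with `sequences` (soft-masked, same names) and
#'   `intervals`, a tibble of masked regions (`seqname`, `start`, `end`,
#'   0-based half-open).
#' @export
mask_frequent_kmers <- function(sequences, k = 16, max_occ = 5) {
  if (k < 1) pf_abort("k must be >= 1")
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  seqs <- toupper(sequences)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))

  kmer_list <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    starts <- seq_len(n - k + 1L)
    substring(s, starts, starts + k - 1L)
  })
  counts <- table(unlist(kmer_list, use.names = FALSE))
  counts <- counts[!grepl("N", names(counts), fixed = TRUE)]
  bad <- names(counts)[counts > max_occ]

  intervals <- list()
  masked <- sequences
  for (nm in names(seqs)) {
    km <- kmer_list[[nm]]
    if (!length(km) || !length(bad)) next
    hit <- which(km %in% bad)
    if (!length(hit)) next
    cover <- logical(nchar(seqs[[nm]]))
    for (h in hit) cover[h:(h + k - 1L)] <- TRUE
    r <- rle(cover)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values)
    intervals[[nm]] <- tibble(seqname = nm,
                              start = starts[on] - 1L, end = ends[on])
    chars <- strsplit(masked[[nm]], "", fixed = TRUE)[[1]]
    chars[cover] <- tolower(chars[cover])
    masked[[nm]] <- paste(chars, collapse = "")
  }
  intervals <- if (length(intervals)) list_rbind(intervals) else
    tibble(seqname = character(), start = integer(), end = integer())
  list(sequences = masked, intervals = intervals)
}

#' @rdname mask_frequent_kmers
#' @param fasta_in,fasta_out,bed_out File paths; reads a FASTA, writes the
#'   soft-masked FASTA and a BED of masked intervals.
#' @export
mask_fasta <- function(fasta_in, fasta_out, bed_out = NULL, k = 16,
                       max_occ = 5) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    pf_abort("package 'Biostrings' is required for FASTA masking")
  }
  seqs <- Biostrings::readDNAStringSet(fasta_in)
  res <- mask_frequent_kmers(setNames(as.character(seqs), names(seqs)),
                             k = k, max_occ = max_occ)
  Biostrings::writeXStringSet(Biostrings::BStringSet(res$sequences), fasta_out)
  if (!is.null(bed_out)) {
    readr::write_tsv(res$intervals, bed_out, col_names = FALSE,
                     progress = FALSE)
  }
  invisible(res$intervals)
}
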
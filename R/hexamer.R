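all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  do.call(paste0, g)
}

#' In-frame hexamer frequency table from training sequences
#'
#' Counts 6-mers at step 3 (frame 0) across a set of sequences, adds a
#' pseudocount to every one of the 4096 hexamers and normalises to
#' frequencies. Used to build the coding and non-coding background tables for
#' [hexamer_bias()].
#'
#' @param sequences character vector of nucleotide sequences.
#' @param pseudocount added to every hexamer count before normalisation.
#' @return Named numeric vector of 4096 positive frequencies summing to 1.
#' @export
hexamer_frequencies <- function(sequences, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  hx <- all_hexamers()
  counts <- setNames(rep(pseudocount, length(hx)), hx)
  for (s in toupper(sequences)) {
    n <- nchar(s)
    if (n < 6L) next
    starts <- seq.int(1L, n - 5L, by = 3L)
    kmers <- substring(s, starts, starts + 5L)
    kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
    if (length(kmers)) {
      tab <- table(kmers)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
  }
  counts / sum(counts)
}

#' Hexamer usage bias of a sequence
#'
#' The mean log-likelihood ratio log(F_coding(h) / F_noncoding(h)) over the
#' in-frame hexamers of the sequence: read at step 3 within the longest ORF
#' when one exists, otherwise over the whole sequence in frame 0. Positive
#' values indicate coding-like hexamer composition. Hexamers containing N are
#' skipped; if every hexamer is skipped the score is 0 with a warning.
#'
#' @param sequence nucleotide string.
#' @param coding_freqs,noncoding_freqs named frequency vectors covering all
#'   4096 hexamers with positive values (see [hexamer_frequencies()]).
#' @return Mean log frequency ratio (0 when the tables are identical).
#' @export
hexamer_bias <- function(sequence, coding_freqs, noncoding_freqs) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (length(coding_freqs) != 4096L || length(noncoding_freqs) != 4096L) {
    stop("frequency tables must cover all 4096 hexamers")
  }
  if (any(coding_freqs <= 0) || any(noncoding_freqs <= 0)) {
    stop("frequency tables must be pseudo-smoothed to positive values")
  }
  s <- toupper(sequence)
  orf <- find_longest_orf(s)
  if (!is.null(orf)) {
    sub <- if (orf$strand == "+") s else revcomp_chr(s)
    sub <- substr(sub, orf$start + 1L, orf$end)
  } else {
    sub <- s
  }
  n <- nchar(sub)
  if (n < 6L) {
    warning("no scoreable hexamer; returning 0")
    return(0)
  }
  starts <- seq.int(1L, n - 5L, by = 3L)
  kmers <- substring(sub, starts, starts + 5L)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  if (!length(kmers)) {
    warning("all hexamers contained N; returning 0")
    return(0)
  }
  mean(log(unname(coding_freqs[kmers]) / unname(noncoding_freqs[kmers])))
}
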
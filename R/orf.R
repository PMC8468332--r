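#' Find the longest open reading frame in a nucleotide sequence
#'
#' Scans all six reading frames (three on the given strand, three on the
#' reverse complement) for complete ORFs: an ATG start codon followed in-frame
#' by a stop codon (TAA/TAG/TGA) with no internal stop. The stop codon is
#' included in the reported length. Codons containing N break an ORF: no
#' reported ORF spans an ambiguous codon.
#'
#' Ties on length are broken in favour of the forward strand, then the
#' smallest start offset.
#'
#' @param sequence a single nucleotide string (A/C/G/T/N, case-insensitive).
#' @return A list with elements `start`, `end` (0-based half-open offsets on
#'   the reported strand), `strand` (`"+"` or `"-"`), `frame` (0/1/2) and
#'   `length_bp`, or `NULL` when the sequence contains no complete ORF.
#' @examples
#' find_longest_orf("ATGAAATAG")  # 9 bp ORF on the forward strand
#' @export
find_longest_orf <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s_fwd <- toupper(sequence)
  if (grepl("[^ACGTN]", s_fwd)) stop("sequence alphabet restricted to A/C/G/T/N")
  s_rev <- revcomp_chr(s_fwd)
  best <- NULL
  # forward strand scanned first so it wins length ties; within a strand the
  # smallest-start candidate of maximal length is already selected
  for (str in c("+", "-")) {
    s <- if (str == "+") s_fwd else s_rev
    cand <- orf_candidates_one_strand(s)
    if (is.null(cand)) next
    cand$strand <- str
    if (is.null(best) || cand$length_bp > best$length_bp) best <- cand
  }
  if (!is.null(best)) best <- best[c("start", "end", "strand", "frame", "length_bp")]
  best
}

# Longest ORF over the three frames of one strand; smallest start breaks ties.
orf_candidates_one_strand <- function(s) {
  n <- nchar(s)
  best <- NULL
  for (frame in 0:2) {
    if (n - frame < 3L) next
    starts <- seq.int(frame + 1L, n - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    has_n <- grepl("N", codons, fixed = TRUE)
    barrier <- which(is_stop | has_n)
    atg <- which(codons == "ATG")
    if (!length(atg) || !length(barrier)) next
    nxt <- findInterval(atg, barrier) + 1L
    ok <- nxt <= length(barrier)
    if (!any(ok)) next
    atg <- atg[ok]
    stop_idx <- barrier[nxt[ok]]
    valid <- is_stop[stop_idx]
    if (!any(valid)) next
    atg <- atg[valid]
    stop_idx <- stop_idx[valid]
    len_bp <- (stop_idx - atg + 1L) * 3L
    i <- which.max(len_bp)  # first maximum = smallest start within the frame
    cand <- list(
      start = frame + (atg[i] - 1L) * 3L,
      end = frame + stop_idx[i] * 3L,
      frame = frame,
      length_bp = len_bp[i]
    )
    if (is.null(best) || cand$length_bp > best$length_bp ||
        (cand$length_bp == best$length_bp && cand$start < best$start)) {
      best <- cand
    }
  }
  best
}

#' Length of the longest ORF, vectorised over sequences
#'
#' @param sequences character vector of nucleotide sequences.
#' @return Integer vector of longest complete ORF lengths in bp; 0 when a
#'   sequence has no complete ORF.
#' @export
longest_orf_lengths <- function(sequences) {
  vapply(sequences, function(s) {
    o <- find_longest_orf(s)
    if (is.null(o)) 0L else o$length_bp
  }, integer(1), USE.NAMES = FALSE)
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
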
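# Fickett TESTCODE lookup tables: for each base, a probability-of-coding value
# per bin of the position parameter (max codon-position count / (min + 1)) and
# of the content parameter (base fraction), plus per-base weights. Bins are
# searched from the highest threshold down; the last bin catches everything.

.fickett_position_breaks <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)
.fickett_content_breaks <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0)

.fickett_position_prob <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
)
.fickett_position_weight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)

.fickett_content_prob <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
)
.fickett_content_weight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)

fickett_lookup <- function(value, breaks, probs) {
  probs[[match(TRUE, value >= breaks)]]
}

#' Codon-position asymmetry parameter of one base
#'
#' Counts the occurrences of `base` at each of the three codon positions of
#' the sequence (frame 0) and returns max / (min + 1); N positions do not
#' count. Values near 1 indicate no positional periodicity, large values a
#' strong 3-periodic bias typical of coding sequence.
#'
#' @param sequence nucleotide string.
#' @param base one of "A", "C", "G", "T".
#' @return The position parameter (non-negative real).
#' @export
fickett_position_parameter <- function(sequence, base) {
  chs <- strsplit(toupper(sequence), "")[[1]]
  pos <- ((seq_along(chs) - 1L) %% 3L) + 1L
  cnt <- vapply(1:3, function(p) sum(chs[pos == p] == base), integer(1))
  max(cnt) / (min(cnt) + 1)
}

#' Fickett TESTCODE coding-potential score
#'
#' Computes the classic TESTCODE statistic: eight parameters (one position and
#' one content parameter per base) are mapped through empirical
#' probability-of-coding lookup tables and combined as a weighted sum. Higher
#' scores indicate coding-like positional periodicity and composition. The
#' score is case-insensitive and deterministic; N bases are ignored in all
#' counts.
#'
#' @param sequence nucleotide string of length >= 200 nt.
#' @return The TESTCODE score (a weighted sum of eight table probabilities).
#' @examples
#' fickett_score(strrep("ACGTAG", 40))
#' @export
fickett_score <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  if (nchar(s) < 200L) stop("fickett_score requires sequences >= 200 nt")
  chs <- strsplit(s, "")[[1]]
  keep <- chs != "N"
  pos <- ((seq_along(chs) - 1L) %% 3L) + 1L
  chs <- chs[keep]
  pos <- pos[keep]
  total <- length(chs)
  score <- 0
  for (base in c("A", "C", "G", "T")) {
    cnt <- vapply(1:3, function(p) sum(chs[pos == p] == base), integer(1))
    position_par <- max(cnt) / (min(cnt) + 1)
    content_par <- sum(cnt) / total
    score <- score +
      .fickett_position_weight[[base]] *
        fickett_lookup(position_par, .fickett_position_breaks,
                       .fickett_position_prob[[base]]) +
      .fickett_content_weight[[base]] *
        fickett_lookup(content_par, .fickett_content_breaks,
                       .fickett_content_prob[[base]])
  }
  unname(score)
}
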
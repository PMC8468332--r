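#' Build a transcript record table
#'
#' A transcript record set is the unit the discovery cascade operates on: one
#' row per assembled contig, carrying its sequence, mean read coverage and an
#' annotation flag (whether a homology search hit it below the e-value
#' threshold). Contigs shorter than 200 nt are rejected, matching the assembly
#' floor that guarantees every candidate already satisfies the minimal lncRNA
#' length.
#'
#' @param id character vector of unique contig identifiers.
#' @param sequence character vector of nucleotide sequences (A/C/G/T/N,
#'   case-insensitive).
#' @param mean_coverage numeric vector of per-contig mean read coverage;
#'   may be `NA` if unknown (the coverage filter then errors).
#' @param annotated logical vector; `TRUE` when the contig has a homology hit.
#' @return A `data.frame` with columns `id`, `sequence`, `length`,
#'   `mean_coverage`, `annotated`, of class `transcript_records`.
#' @examples
#' transcript_records("c1", strrep("ACGT", 60), mean_coverage = 80)
#' @export
transcript_records <- function(id, sequence,
                               mean_coverage = NA_real_,
                               annotated = FALSE) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (anyDuplicated(id)) {
    stop("duplicated transcript ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (length(sequence) != length(id)) {
    stop("'id' and 'sequence' must have equal length")
  }
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    stop("sequence alphabet restricted to A/C/G/T/N; offending ids: ",
         paste(id[bad], collapse = ", "))
  }
  len <- nchar(sequence)
  if (any(len < 200L)) {
    stop("all transcripts must be >= 200 nt (assembly floor); offending ids: ",
         paste(id[len < 200L], collapse = ", "))
  }
  out <- data.frame(
    id = id,
    sequence = sequence,
    length = len,
    mean_coverage = rep_len(as.numeric(mean_coverage), length(id)),
    annotated = rep_len(as.logical(annotated), length(id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("transcript_records", "data.frame")
  out
}

# Keep the class through row subsetting.
#' @export
`[.transcript_records` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- c("transcript_records", "data.frame")
  out
}

#' @export
print.transcript_records <- function(x, ...) {
  cat(sprintf("<transcript_records> %d contigs, lengths %d-%d nt\n",
              nrow(x), if (nrow(x)) min(x$length) else 0L,
              if (nrow(x)) max(x$length) else 0L))
  invisible(x)
}
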
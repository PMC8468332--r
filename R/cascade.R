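#' Remove contigs annotated by homology
#'
#' Drops every contig with at least one homology hit below the e-value
#' threshold, mirroring the first step of the lncRNA mining cascade (annotated
#' contigs cannot be lncRNAs). Input order of the retained records is
#' preserved.
#'
#' @param records a [transcript_records] table.
#' @param hit_table homology hits as read by [read_blast_hits()] (12-column
#'   tabular dialect); may have zero rows.
#' @param evalue e-value threshold; hits with `evalue < threshold` mark a
#'   contig as annotated.
#' @return The retained records.
#' @export
filter_annotated <- function(records, hit_table, evalue = 1e-3) {
  annotated_ids <- unique(hit_table$qseqid[hit_table$evalue < evalue])
  out <- records[!(records$id %in% annotated_ids), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove low-coverage contigs
#'
#' Retains contigs with mean coverage at or above the floor; contigs with
#' `mean_coverage < min_cov` are deleted (the boundary value is kept).
#'
#' @param records a [transcript_records] table.
#' @param min_cov coverage floor (default 50).
#' @return The retained records.
#' @export
filter_coverage <- function(records, min_cov = 50) {
  if (anyNA(records$mean_coverage)) {
    stop("missing mean_coverage for: ",
         paste(records$id[is.na(records$mean_coverage)], collapse = ", "))
  }
  out <- records[records$mean_coverage >= min_cov, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove contigs with a long open reading frame
#'
#' Discards contigs whose longest complete ORF exceeds `max_orf` bp; contigs
#' with an ORF of exactly `max_orf` bp, or with no complete ORF at all, are
#' retained.
#'
#' @param records a [transcript_records] table.
#' @param max_orf ORF length ceiling in bp (default 200).
#' @param orf_lengths optional precomputed vector from
#'   [longest_orf_lengths()] aligned with `records`.
#' @return The retained records.
#' @export
filter_orf_length <- function(records, max_orf = 200, orf_lengths = NULL) {
  if (is.null(orf_lengths)) orf_lengths <- longest_orf_lengths(records$sequence)
  out <- records[orf_lengths <= max_orf, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full lncRNA discovery cascade
#'
#' Applies, in order: annotation filter, coverage filter, ORF-length filter,
#' and the coding-potential filter (predicted coding probability at or above
#' the model cutoff discards a contig). Because each stage is an independent
#' predicate on a contig, the result equals the intersection of the per-stage
#' keep-sets; the staged order is kept for its interpretable per-stage counts.
#'
#' @param records a [transcript_records] table.
#' @param hit_table homology hits (see [filter_annotated()]).
#' @param model a `coding_model` carrying hexamer tables
#'   (see [build_coding_model()]).
#' @param evalue,min_cov,max_orf stage thresholds.
#' @param cutoff coding-probability cutoff; defaults to the model's.
#' @return A list with `lncrnas` (the retained records) and `report`
#'   (a `cascade_report` of per-stage counts and the final percentage).
#' @export
run_cascade <- function(records, hit_table, model,
                        evalue = 1e-3, min_cov = 50, max_orf = 200,
                        cutoff = NULL) {
  cutoff <- cutoff %||% model$cutoff
  n0 <- nrow(records)
  s1 <- filter_annotated(records, hit_table, evalue = evalue)
  s2 <- filter_coverage(s1, min_cov = min_cov)
  s3 <- filter_orf_length(s2, max_orf = max_orf)
  if (nrow(s3)) {
    prob <- predict(model, records = s3)
    s4 <- s3[prob < cutoff, , drop = FALSE]
    rownames(s4) <- NULL
  } else {
    s4 <- s3
  }
  report <- structure(
    list(stages = data.frame(
      stage = c("input", "annotation_filter", "coverage_filter",
                "orf_filter", "coding_potential_filter"),
      n = c(n0, nrow(s1), nrow(s2), nrow(s3), nrow(s4))
    ),
    thresholds = list(evalue = evalue, min_cov = min_cov,
                      max_orf = max_orf, cutoff = cutoff)),
    class = "cascade_report"
  )
  list(lncrnas = s4, report = report)
}

#' @export
print.cascade_report <- function(x, ...) {
  n <- x$stages$n
  total <- n[1]
  cat("<cascade_report> lncRNA discovery cascade\n")
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-24s %8d (%.2f%%)\n", x$stages$stage[i], n[i],
                if (total > 0) 100 * n[i] / total else 0))
  }
  invisible(x)
}

#' Percentage of input contigs surviving the cascade
#'
#' @param report a `cascade_report`.
#' @return `100 * putative / total`, recomputed from the stage counts.
#' @export
cascade_percentage <- function(report) {
  n <- report$stages$n
  if (n[1] == 0) return(0)
  100 * n[length(n)] / n[1]
}
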
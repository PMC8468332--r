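#' Place transcripts on a genome
#'
#' Either searches a genome for exact full-length matches of each transcript
#' (forward then reverse-complement) or consumes precomputed alignments from a
#' BED/minimal-SAM reader. At most one placement is kept per transcript: the
#' best by alignment length, ties resolved by first chromosome in genome
#' order, then lowest start.
#'
#' @param records [transcript_records] of putative lncRNAs.
#' @param genome a named `DNAStringSet` of chromosome sequences (exact-match
#'   mode), or `NULL` when `alignments` are given.
#' @param alignments optional placement `data.frame` from
#'   [read_bed_placements()] or [read_sam_minimal()].
#' @return A list with `placements` (`data.frame`: `id`, `chrom`, `start`,
#'   `end` 0-based half-open, `strand`), `unplaced` (character ids) and
#'   `placed_fraction`.
#' @export
place_transcripts <- function(records, genome = NULL, alignments = NULL) {
  if (is.null(genome) && is.null(alignments)) {
    stop("supply either a genome or precomputed alignments")
  }
  if (!is.null(alignments)) {
    if (!is.null(genome)) {
      unknown <- setdiff(unique(alignments$chrom), names(genome))
      if (length(unknown)) {
        stop("alignment references unknown chromosome: ",
             paste(unknown, collapse = ", "))
      }
    }
    aln <- alignments[alignments$id %in% records$id, , drop = FALSE]
    chrom_rank <- if (!is.null(genome)) match(aln$chrom, names(genome)) else
      match(aln$chrom, sort(unique(aln$chrom)))
    ord <- order(aln$id, -aln$aln_length, chrom_rank, aln$start)
    aln <- aln[ord, , drop = FALSE]
    best <- aln[!duplicated(aln$id), c("id", "chrom", "start", "end", "strand")]
  } else {
    best <- exact_match_placements(records, genome)
  }
  rownames(best) <- NULL
  unplaced <- setdiff(records$id, best$id)
  list(placements = best, unplaced = unplaced,
       placed_fraction = if (nrow(records)) nrow(best) / nrow(records) else 0)
}

exact_match_placements <- function(records, genome) {
  hits <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    found <- NULL
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") records$sequence[i] else
        revcomp_chr(records$sequence[i])
      m <- Biostrings::vmatchPattern(pat, genome)
      for (ci in seq_along(m)) {
        if (length(m[[ci]])) {
          st <- min(IRanges::start(m[[ci]])) - 1L
          cand <- data.frame(id = records$id[i], chrom = names(genome)[ci],
                             start = st, end = st + records$length[i],
                             strand = strand, stringsAsFactors = FALSE)
          if (is.null(found)) found <- cand
        }
      }
      if (!is.null(found)) break  # forward-strand full-length match wins
    }
    hits[[i]] <- found
  }
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) {
    return(data.frame(id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Extract protein-coding genes within a window of each placed lncRNA
#'
#' Links a placed lncRNA to every gene on the same chromosome whose interval
#' intersects the lncRNA interval widened by `window` bp on both sides,
#' strand-agnostically. The boundary is inclusive: a gap of exactly `window`
#' bp still links. Distance is 0 for overlapping intervals, otherwise the gap
#' length; the relation is reported relative to the lncRNA orientation
#' (upstream = the gene lies on the lncRNA's 5' side).
#'
#' @param placements placement `data.frame` (0-based half-open).
#' @param genes gene `data.frame` as from [read_gff3_genes()].
#' @param window flank size in bp (default 10000).
#' @return `data.frame` with `lncrna_id`, `gene_id`, `distance_bp`,
#'   `relation` (`upstream`/`downstream`/`overlapping`).
#' @export
extract_neighbors <- function(placements, genes, window = 10000) {
  if (window < 0) stop("window must be non-negative")
  if (!nrow(placements) || !nrow(genes)) {
    return(data.frame(lncrna_id = character(), gene_id = character(),
                      distance_bp = integer(), relation = character(),
                      stringsAsFactors = FALSE))
  }
  lgr <- GenomicRanges::GRanges(placements$chrom,
                                IRanges::IRanges(placements$start + 1L,
                                                 placements$end))
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start + 1L, genes$end))
  ov <- GenomicRanges::findOverlaps(lgr, ggr, maxgap = window)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  dist <- GenomicRanges::distance(lgr[qi], ggr[si])
  dist[is.na(dist)] <- 0L
  # genomic side of the gene relative to the lncRNA, mapped through strand
  gene_left <- genes$end[si] <= placements$start[qi]
  gene_right <- genes$start[si] >= placements$end[qi]
  lstrand <- placements$strand[qi]
  lstrand[is.na(lstrand) | lstrand == "*"] <- "+"
  relation <- rep("overlapping", length(qi))
  up <- (gene_left & lstrand == "+") | (gene_right & lstrand == "-")
  dn <- (gene_right & lstrand == "+") | (gene_left & lstrand == "-")
  relation[up] <- "upstream"
  relation[dn] <- "downstream"
  out <- data.frame(lncrna_id = placements$id[qi],
                    gene_id = genes$gene_id[si],
                    distance_bp = as.integer(dist),
                    relation = relation,
                    stringsAsFactors = FALSE)
  out <- out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Venn partition of up to three labelled sets
#'
#' Computes the `2^k - 1` disjoint membership regions of 1-3 labelled sets,
#' with counts, percentages of the union, and element memberships. Regions
#' are disjoint by construction and their union equals the input union.
#'
#' @param sets named list of 1-3 character vectors.
#' @return A `venn_partition` object: `data.frame` with `region`, `count`,
#'   `pct`, plus a `members` attribute (named list of region members).
#' @examples
#' venn_partition(list(A = c("x", "y"), B = c("y", "z")))
#' @export
venn_partition <- function(sets) {
  k <- length(sets)
  if (k < 1L || k > 3L) stop("venn_partition takes 1-3 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be named")
  }
  sets <- lapply(sets, function(x) unique(as.character(x)))
  universe <- unique(unlist(sets, use.names = FALSE))
  labels <- names(sets)
  combos <- unlist(lapply(seq_len(k), function(m) {
    asplit(utils::combn(labels, m), 2)
  }), recursive = FALSE)
  membership <- matrix(FALSE, length(universe), k,
                       dimnames = list(universe, labels))
  for (lb in labels) membership[, lb] <- universe %in% sets[[lb]]
  members <- lapply(combos, function(cmb) {
    inside <- rowSums(membership[, cmb, drop = FALSE]) == length(cmb)
    outside <- rowSums(membership[, setdiff(labels, cmb), drop = FALSE]) == 0
    universe[inside & outside]
  })
  region <- vapply(combos, paste, character(1), collapse = "&")
  names(members) <- region
  counts <- lengths(members)
  out <- data.frame(region = region, count = as.integer(counts),
                    pct = if (length(universe)) 100 * counts / length(universe)
                          else rep(0, length(counts)),
                    stringsAsFactors = FALSE)
  attr(out, "members") <- members
  attr(out, "union_size") <- length(universe)
  class(out) <- c("venn_partition", "data.frame")
  out
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("<venn_partition> %d disjoint regions, union = %d\n",
              nrow(x), attr(x, "union_size")))
  print.data.frame(transform(x, pct = round(pct, 1)))
  invisible(x)
}
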
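# File-format boundary. Internally all genomic intervals are 0-based
# half-open; conversions happen only here (GFF3 is 1-based closed on disk,
# BED 0-based half-open, SAM 1-based).

#' Read assembled contigs with coverage into a record table
#'
#' @param fasta path to a contig FASTA file.
#' @param coverage_tsv path to a two-column TSV (`id`, `mean_coverage`);
#'   optional.
#' @return A [transcript_records] table.
#' @export
read_contigs <- function(fasta, coverage_tsv = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  cov <- rep(NA_real_, length(ids))
  if (!is.null(coverage_tsv)) {
    tab <- read.delim(coverage_tsv, stringsAsFactors = FALSE)
    cov <- tab$mean_coverage[match(ids, tab$id)]
  }
  transcript_records(ids, as.character(seqs), mean_coverage = cov)
}

#' Write records to FASTA
#' @param records a [transcript_records] table.
#' @param path output FASTA path.
#' @export
write_contigs <- function(records, path) {
  x <- Biostrings::DNAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.blast_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read a 12-column tabular homology hit file
#'
#' Parses the standard 12-column BLAST tabular dialect. Malformed rows (wrong
#' field count or non-numeric numeric fields) raise an error naming the line.
#'
#' @param path hit file path.
#' @return `data.frame` with the 12 standard columns.
#' @export
read_blast_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    out <- as.data.frame(setNames(
      c(list(character(), character()), rep(list(numeric()), 10)),
      .blast_cols))
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    stop("malformed hit row (expected 12 tab-separated fields) at line ",
         which(nf != 12L)[1])
  }
  m <- do.call(rbind, parts)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 10)
  bad <- which(!complete.cases(num))
  if (length(bad)) {
    stop("malformed hit row (non-numeric field) at line ", bad[1])
  }
  out <- data.frame(qseqid = m[, 1], sseqid = m[, 2], num,
                    stringsAsFactors = FALSE)
  names(out) <- .blast_cols
  out
}

#' Write homology hits in the 12-column tabular dialect
#' @param hits `data.frame` with the 12 standard columns.
#' @param path output path.
#' @export
write_blast_hits <- function(hits, path) {
  write.table(hits[, .blast_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' Imports gene records from a GFF3 file and converts them to the internal
#' 0-based half-open convention. GO term ids are taken from the
#' `Ontology_term` attribute when present.
#'
#' @param path GFF3 file path.
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, and a list-column `go` of GO ids.
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  mc <- GenomicRanges::mcols(gr)
  go <- if ("Ontology_term" %in% names(mc)) {
    lapply(mc$Ontology_term, as.character)
  } else {
    rep(list(character()), length(gr))
  }
  out <- data.frame(
    gene_id = as.character(mc$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  out$go <- go
  out
}

#' Write gene annotations to GFF3
#'
#' @param genes `data.frame` as returned by [read_gff3_genes()] (0-based
#'   half-open `start`/`end`; optional list-column `go`).
#' @param path output GFF3 path.
#' @export
write_gff3_genes <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$source <- "lncmine"
  gr$ID <- genes$gene_id
  if (!is.null(genes$go)) {
    gr$Ontology_term <- S4Vectors::SimpleList(lapply(genes$go, as.character))
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read genome placements from BED
#'
#' @param path BED file path (BED6 or narrower).
#' @return `data.frame` with `id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `aln_length`.
#' @export
read_bed_placements <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    id = as.character(gr$name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "*", "+",
                    as.character(GenomicRanges::strand(gr))),
    stringsAsFactors = FALSE
  ) |> transform(aln_length = end - start)
}

#' Write genome placements to BED6
#' @param placements placement `data.frame` (0-based half-open).
#' @param path output BED path.
#' @export
write_bed_placements <- function(placements, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = placements$chrom,
    ranges = IRanges::IRanges(start = placements$start + 1L,
                              end = placements$end),
    strand = placements$strand
  )
  gr$name <- placements$id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a minimal SAM file of transcript placements
#'
#' Parses only the QNAME/FLAG/RNAME/POS/CIGAR subset of SAM. Unmapped records
#' (flag 0x4) are skipped; strand comes from flag 0x10; the aligned reference
#' length is the sum of M/=/X/D/N CIGAR operations.
#'
#' @param path SAM file path.
#' @return Placement `data.frame` (0-based half-open) as in
#'   [read_bed_placements()].
#' @export
read_sam_minimal <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L) stop("malformed SAM row at line ", i)
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    if (is.na(flag) || is.na(pos)) stop("malformed SAM row at line ", i)
    if (bitwAnd(flag, 4L) != 0L) return(NULL)
    ops <- gregexpr("(\\d+)([MIDNSHP=X])", f[6])[[1]]
    lens <- as.integer(regmatches(f[6], gregexpr("\\d+", f[6]))[[1]])
    chars <- regmatches(f[6], gregexpr("[MIDNSHP=X]", f[6]))[[1]]
    ref_len <- sum(lens[chars %in% c("M", "=", "X", "D", "N")])
    data.frame(id = f[1], chrom = f[3], start = pos - 1L,
               end = pos - 1L + ref_len,
               strand = if (bitwAnd(flag, 16L) != 0L) "-" else "+",
               aln_length = ref_len, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), aln_length = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Read a count matrix from TSV
#'
#' @param path TSV with feature ids in the first column, one column per
#'   sample.
#' @return Integer matrix with feature rownames.
#' @export
read_counts_tsv <- function(path) {
  tab <- read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(tab)
}

#' Write a count (or numeric) matrix to TSV
#' @param mat matrix with rownames and colnames.
#' @param path output path.
#' @param id_col name of the leading id column.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "feature_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-GO (or gene-to-pathway) map from TSV
#'
#' @param path TSV with columns `gene_id` and `term` (one row per pair).
#' @return Named list mapping gene id to character vector of term ids.
#' @export
read_gene2go_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  split(tab$term, tab$gene_id)
}

#' Write a gene-to-term map to TSV
#' @param map named list gene id -> character vector of term ids.
#' @param path output path.
#' @export
write_gene2go_tsv <- function(map, path) {
  tab <- data.frame(
    gene_id = rep(names(map), lengths(map)),
    term = unlist(map, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
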
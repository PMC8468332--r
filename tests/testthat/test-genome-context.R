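test_that("exact-match placement finds known positions and reports unplaced", {
  set.seed(17)
  chr1 <- random_seq(5000)
  tx <- substr(chr1, 1001, 1300)
  genome <- Biostrings::DNAStringSet(c(chr1 = chr1, chr2 = random_seq(3000)))
  recs <- transcript_records(c("hit", "miss"),
                             c(tx, random_seq(300)),
                             mean_coverage = 100)
  res <- place_transcripts(recs, genome = genome)
  expect_identical(res$placements$id, "hit")
  expect_identical(res$placements$start, 1000L)
  expect_identical(res$placements$end, 1300L)
  expect_identical(res$unplaced, "miss")
  expect_equal(res$placed_fraction, 0.5)
})

test_that("synthetic placeable fraction is recovered exactly", {
  cfg <- small_cfg(n_noncoding_contigs = 100L, placeable_fraction = 0.33)
  g <- generate_genome(cfg)
  tx <- generate_transcripts(cfg, g)
  nc <- tx$records[tx$truth$contigs$class == "noncoding", ]
  res <- place_transcripts(nc, genome = g$genome)
  expect_equal(res$placed_fraction, 0.33)
  expect_setequal(res$placements$id,
                  tx$truth$contigs$id[tx$truth$contigs$placed])
  # placements agree with the planted truth coordinates
  truth_placed <- tx$truth$contigs[tx$truth$contigs$placed, ]
  m <- match(truth_placed$id, res$placements$id)
  expect_identical(res$placements$start[m], truth_placed$start)
  expect_identical(res$placements$chrom[m], truth_placed$chrom)
})

test_that("precomputed BED/SAM alignments drive placement and best-hit choice", {
  aln <- data.frame(
    id = c("t1", "t1", "t2"),
    chrom = c("chr1", "chr2", "chr1"),
    start = c(100L, 40L, 9L),
    end = c(300L, 340L, 209L),
    strand = c("+", "+", "-"),
    aln_length = c(200L, 300L, 200L),
    stringsAsFactors = FALSE)
  recs <- transcript_records(c("t1", "t2", "t3"),
                             replicate(3, strrep("ACGT", 75)),
                             mean_coverage = 100)
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 1000),
                                       chr2 = strrep("C", 1000)))
  res <- place_transcripts(recs, genome = genome, alignments = aln)
  # t1: longer alignment on chr2 wins
  expect_identical(res$placements$chrom[res$placements$id == "t1"], "chr2")
  expect_setequal(res$unplaced, "t3")
  bad <- aln
  bad$chrom[1] <- "chrX"
  expect_error(place_transcripts(recs, genome = genome, alignments = bad),
               "unknown chromosome")
})

test_that("minimal SAM parsing extracts placements from text", {
  sam <- c("@HD\tVN:1.6",
           "@SQ\tSN:chr1\tLN:5000",
           "t1\t0\tchr1\t101\t60\t100M",
           "t2\t16\tchr1\t201\t60\t50M10D40M",
           "t3\t4\t*\t0\t0\t*")
  f <- withr::local_tempfile(lines = sam, fileext = ".sam")
  pl <- read_sam_minimal(f)
  expect_identical(pl$id, c("t1", "t2"))
  expect_identical(pl$start, c(100L, 200L))
  expect_identical(pl$end, c(200L, 300L))  # 50M 10D 40M spans 100 bp
  expect_identical(pl$strand, c("+", "-"))
})

test_that("neighbour extraction honours the inclusive 10-kb boundary", {
  pl <- data.frame(id = "l1", chrom = "chr1", start = 20000L, end = 20500L,
                   strand = "+", stringsAsFactors = FALSE)
  genes <- data.frame(
    gene_id = c("exact", "toofar", "overlap", "inside_window"),
    chrom = "chr1",
    start = c(30500L, 30501L, 20400L, 5000L),
    end = c(31000L, 31001L, 21000L, 10000L),
    strand = "+", stringsAsFactors = FALSE)
  nb <- extract_neighbors(pl, genes, window = 10000)
  expect_setequal(nb$gene_id, c("exact", "overlap", "inside_window"))
  expect_identical(nb$distance_bp[nb$gene_id == "exact"], 10000L)
  expect_identical(nb$distance_bp[nb$gene_id == "overlap"], 0L)
  expect_identical(nb$relation[nb$gene_id == "overlap"], "overlapping")
  expect_identical(nb$relation[nb$gene_id == "exact"], "downstream")
  expect_identical(nb$relation[nb$gene_id == "inside_window"], "upstream")
  expect_error(extract_neighbors(pl, genes, window = -1), "non-negative")
})

test_that("neighbour extraction equals the brute-force interval scan", {
  set.seed(23)
  n <- 120
  pl <- data.frame(id = sprintf("l%03d", 1:n),
                   chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                   start = sample(0:200000, n), stringsAsFactors = FALSE)
  pl$end <- pl$start + sample(200:2000, n, replace = TRUE)
  pl$strand <- sample(c("+", "-"), n, replace = TRUE)
  genes <- data.frame(gene_id = sprintf("g%03d", 1:n),
                      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                      start = sample(0:200000, n), stringsAsFactors = FALSE)
  genes$end <- genes$start + sample(500:3000, n, replace = TRUE)
  genes$strand <- "+"
  mine <- extract_neighbors(pl, genes, window = 10000)
  oracle <- oracle_neighbors(pl, genes, 10000L)
  expect_identical(mine[, c("lncrna_id", "gene_id", "distance_bp")],
                   `rownames<-`(oracle, NULL))
  # widening the window never removes links
  wider <- extract_neighbors(pl, genes, window = 20000)
  expect_true(all(paste(mine$lncrna_id, mine$gene_id) %in%
                    paste(wider$lncrna_id, wider$gene_id)))
})

test_that("venn partition is disjoint, conserves the union and handles ties", {
  v <- venn_partition(list(A = c("x", "y", "z"), B = c("y", "z", "w"),
                           C = c("z", "q")))
  expect_identical(nrow(v), 7L)
  expect_identical(sum(v$count), attr(v, "union_size"))
  members <- attr(v, "members")
  expect_identical(sort(unique(unlist(members))), sort(c("x","y","z","w","q")))
  expect_identical(sum(duplicated(unlist(members))), 0L)
  expect_identical(members[["A&B&C"]], "z")

  # degenerate: identical sets collapse into the all-common region
  v2 <- venn_partition(list(A = c("a", "b"), B = c("a", "b"), C = c("a", "b")))
  expect_identical(v2$count[v2$region == "A&B&C"], 2L)
  expect_true(all(v2$count[v2$region != "A&B&C"] == 0L))
})

test_that("GFF3 intervals survive a write/read round trip exactly", {
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = c("chr1", "chr2"),
    start = c(0L, 999L), end = c(1500L, 2000L), strand = c("+", "-"),
    stringsAsFactors = FALSE)
  genes$go <- list(c("GO:0008150"), c("GO:0006952", "GO:0003674"))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3_genes(genes, f)
  back <- read_gff3_genes(f)
  expect_identical(back$gene_id, genes$gene_id)
  expect_identical(back$start, genes$start)
  expect_identical(back$end, genes$end)
  expect_identical(back$strand, genes$strand)
  expect_identical(lapply(back$go, sort), lapply(genes$go, sort))
})
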
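test_that("generators are deterministic and leave the RNG state alone", {
  cfg <- small_cfg()
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$gene2go, g2$gene2go)
  t1 <- generate_transcripts(cfg, g1)
  t2 <- generate_transcripts(cfg, g2)
  expect_identical(t1$records$sequence, t2$records$sequence)
  expect_identical(t1$truth$contigs, t2$truth$contigs)
  c1 <- generate_counts(cfg, t1$truth)
  c2 <- generate_counts(cfg, t2$truth)
  expect_identical(c1$counts, c2$counts)
  q1 <- generate_qpcr(cfg, t1$truth)
  q2 <- generate_qpcr(cfg, t2$truth)
  expect_identical(q1$ct, q2$ct)

  set.seed(555)
  before <- runif(1)
  set.seed(555)
  invisible(generate_genome(cfg))
  expect_identical(runif(1), before)
})

test_that("genome packing respects bounds and rejects the infeasible", {
  cfg <- small_cfg(n_genes = 0L)
  expect_identical(nrow(generate_genome(cfg)$genes), 0L)

  g <- generate_genome(small_cfg(n_genes = 50L))
  genes <- g$genes
  widths <- setNames(Biostrings::width(g$genome), names(g$genome))
  for (i in seq_len(nrow(genes))) {  # exhaustive bounds scan
    expect_gte(genes$start[i], 0L)
    expect_lte(genes$end[i], widths[[genes$chrom[i]]])
    expect_lt(genes$start[i], genes$end[i])
  }
  # non-overlap within each chromosome
  for (cc in unique(genes$chrom)) {
    sub <- genes[genes$chrom == cc, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1) {
      expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
    }
  }
  expect_true(all(lengths(g$gene2go) >= 1L))

  expect_error(generate_genome(small_cfg(n_genes = 400L, chrom_length = 30000L)),
               "infeasible packing")
})

test_that("transcript classes obey their construction constraints", {
  sim <- small_sim()
  truth <- sim$truth$contigs
  orf_len <- longest_orf_lengths(sim$records$sequence)
  expect_true(all(orf_len[truth$class == "coding"] > 200L))
  expect_true(all(orf_len[truth$class == "noncoding"] <= 200L))
  expect_true(all(sim$records$length >= 200L))
  expect_identical(truth$annotated, truth$class == "coding")

  # placeable count forced by the rounding rule
  cfg <- small_cfg(n_noncoding_contigs = 100L, placeable_fraction = 0.33)
  tx <- generate_transcripts(cfg, generate_genome(cfg))
  expect_identical(sum(tx$truth$contigs$placed), 33L)

  # empty coding class
  cfg0 <- small_cfg(n_coding_contigs = 0L)
  tx0 <- generate_transcripts(cfg0, generate_genome(cfg0))
  expect_identical(sum(tx0$truth$contigs$class == "coding"), 0L)
})

test_that("planted placements and cis pairs sit where the truth says", {
  sim <- small_sim()
  truth <- sim$truth$contigs
  chroms <- as.character(sim$genome$genome)
  placed <- truth[truth$placed, ]
  for (i in seq_len(nrow(placed))) {
    sub <- substr(chroms[[placed$chrom[i]]], placed$start[i] + 1L,
                  placed$end[i])
    expect_identical(sub, sim$records$sequence[match(placed$id[i],
                                                     sim$records$id)])
  }
  # every cis pair within 10 kb of its partner gene, brute-force interval math
  genes <- sim$truth$genes
  for (i in seq_len(nrow(sim$truth$cis_pairs))) {
    l <- truth[truth$id == sim$truth$cis_pairs$lncrna_id[i], ]
    gn <- genes[genes$gene_id == sim$truth$cis_pairs$gene_id[i], ]
    expect_true(l$placed && l$class == "noncoding")
    expect_identical(l$chrom, gn$chrom)
    gap <- max(gn$start - l$end, l$start - gn$end, 0L)
    expect_lte(gap, 10000L)
  }
  # DE never planted for the control: lfc columns exist only for stimuli
  expect_false(any(grepl("lfc_control|de_control", names(truth))))
})

test_that("counts follow the planted NB law", {
  cfg <- small_cfg()
  sim <- small_sim()

  # Poisson limit: variance/mean ratio near 1
  cfgp <- small_cfg(dispersion = 1e-9)
  cnt <- generate_counts(cfgp, sim$truth)
  ctrl <- cnt$counts[, cnt$condition == "control", drop = FALSE]
  # pool across features: mean of per-feature var/mean ratios
  mu <- rowMeans(ctrl)
  vr <- apply(ctrl, 1, var)
  keep <- mu > 20
  expect_lt(abs(mean(vr[keep] / mu[keep]) - 1), 0.1)

  # no planted fold change: control-condition mean within 3 SE of base mean
  cnt2 <- generate_counts(cfg, sim$truth)
  ctrl2 <- cnt2$counts[, cnt2$condition == "control", drop = FALSE]
  base <- sim$truth$contigs$base_mean
  n_feat <- length(base)
  m <- rowMeans(ctrl2)[seq_len(n_feat)]
  se <- sqrt((base + cfg$dispersion * base^2) / ncol(ctrl2))
  expect_gt(mean(abs(m - base) <= 3 * se), 0.95)

  # non-DE features share the generating law across all conditions:
  # regenerating with all planted changes removed leaves their counts identical
  truth0 <- sim$truth
  for (s in truth0$stimuli) {
    truth0$contigs[[paste0("lfc_", s)]] <- 0
    truth0$genes[[paste0("lfc_", s)]] <- 0
  }
  cnt0 <- generate_counts(cfg, truth0)
  nonde <- sim$truth$contigs$pattern == "none"
  expect_identical(cnt2$counts[which(nonde), ], cnt0$counts[which(nonde), ])

  # coverage mixture puts roughly the configured fraction below 50
  cfg_big <- small_cfg(n_coding_contigs = 300L, n_noncoding_contigs = 300L,
                       low_coverage_fraction = 0.2)
  tx <- generate_transcripts(cfg_big, generate_genome(cfg_big))
  frac <- mean(tx$truth$contigs$mean_coverage < 50)
  expect_lt(abs(frac - 0.2), 0.06)
})

test_that("qPCR arm encodes the planted expression at the given efficiency", {
  # zero-noise generator: Ct differences recover the planted log2 fold change
  cfg0 <- small_cfg(ct_noise_sd = 0, qpcr_bio_sdlog = 1e-12)
  tx <- generate_transcripts(cfg0, generate_genome(cfg0))
  qp <- generate_qpcr(cfg0, tx$truth)
  ct <- qp$ct
  tgt <- qp$targets$target[1]
  stim <- qp$targets$stimulus[1]
  lfc <- tx$truth$contigs[[paste0("lfc_", stim)]][
    match(tgt, tx$truth$contigs$id)]
  m_ctrl <- mean(ct$ct[ct$target == tgt & ct$condition == "control"])
  m_stim <- mean(ct$ct[ct$target == tgt & ct$condition == stim])
  # E = 2: Ct drops by exactly the planted log2 FC (halving -> +1 cycle)
  expect_equal(m_ctrl - m_stim, lfc, tolerance = 1e-6)

  # dilution series slope is exactly -1/log10(2) at zero noise
  ser <- qp$dilution[qp$dilution$target == qp$reference, ]
  fit <- lm(ct ~ log10(dilution), data = ser)
  expect_equal(unname(coef(fit)[2]), -1 / log10(2), tolerance = 1e-6)

  # reference gene is non-DE by construction
  m_ref <- tapply(ct$ct[ct$target == qp$reference],
                  ct$condition[ct$target == qp$reference], mean)
  expect_lt(max(m_ref) - min(m_ref), 1e-6)

  # 4 targets per stimulus, all planted DE for that stimulus
  expect_identical(as.integer(table(qp$targets$stimulus)[tx$truth$stimuli]),
                   rep(4L, 3))

  # too few DE lncRNAs -> explicit error
  cfg_poor <- small_cfg(de_fraction_per_condition = c(LPS = 0.02,
                                                      polyIC = 0.0,
                                                      betaglucan = 0.0),
                        common_de_fraction = 0)
  txp <- generate_transcripts(cfg_poor, generate_genome(cfg_poor))
  expect_error(generate_qpcr(cfg_poor, txp$truth), "fewer than 4")
})

test_that("synthetic inputs round-trip through the package readers", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  paths <- write_synthetic_inputs(sim, dir)

  recs <- read_contigs(paths[["contigs.fasta"]], paths[["coverage.tsv"]])
  expect_identical(recs$sequence, sim$records$sequence)
  expect_equal(recs$mean_coverage, sim$records$mean_coverage,
               tolerance = 1e-8)

  hits <- read_blast_hits(paths[["hits.tsv"]])
  expect_identical(hits$qseqid, sim$hits$qseqid)
  expect_equal(hits$evalue, sim$hits$evalue, tolerance = 1e-10)

  genes <- read_gff3_genes(paths[["genes.gff3"]])
  expect_identical(genes$gene_id, sim$genome$genes$gene_id)
  expect_identical(genes$start, sim$genome$genes$start)
  expect_identical(genes$end, sim$genome$genes$end)
  expect_identical(lapply(genes$go, sort),
                   unname(lapply(sim$genome$gene2go[genes$gene_id], sort)))

  bed <- read_bed_placements(paths[["placements.bed"]])
  placed <- sim$truth$contigs[sim$truth$contigs$placed, ]
  expect_setequal(bed$id, placed$id)
  expect_identical(bed$start[match(placed$id, bed$id)], placed$start)

  cnt <- read_counts_tsv(paths[["counts.tsv"]])
  expect_identical(unname(cnt), unname(sim$counts$counts))

  cfg_echo <- jsonlite::read_json(paths[["config.json"]], simplifyVector = TRUE)
  expect_equal(cfg_echo$seed, sim$cfg$seed)
  expect_equal(cfg_echo$dispersion, sim$cfg$dispersion)
  expect_identical(cfg_echo$conditions, sim$cfg$conditions)
})
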
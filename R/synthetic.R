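#' Configuration for the synthetic PAMP-stimulation experiment
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the statistical structure the analysis assumes: a four-condition design
#' (control plus LPS, poly I:C and beta-glucans, three replicates each),
#' coding contigs with long codon-biased ORFs, non-coding contigs with short
#' ORFs of which about a third can be placed on the genome, NB-distributed
#' counts with condition-specific planted fold changes dominated by LPS,
#' cis-correlated lncRNA-gene pairs within 10 kb, and Ct values consistent
#' with the planted expression at a given amplification efficiency.
#'
#' @param seed master seed; per-stage child seeds are derived from it.
#' @param n_chromosomes,chrom_length genome shape (bp).
#' @param n_genes number of protein-coding genes packed into the genome.
#' @param n_coding_contigs,n_noncoding_contigs contig class sizes.
#' @param placeable_fraction fraction of non-coding contigs copied verbatim
#'   from the genome (and hence placeable by exact match).
#' @param n_replicates biological replicates per condition.
#' @param conditions ordered condition labels; the first is the control.
#' @param de_fraction_per_condition named fractions of contigs planted DE
#'   exclusively in each stimulus; LPS carries the largest response.
#' @param common_de_fraction fraction planted DE in all three stimuli with a
#'   shared fold change.
#' @param gene_de_fraction fraction of genes planted DE independently of any
#'   lncRNA pairing.
#' @param down_fraction named per-stimulus probability that a planted change
#'   is a down-regulation.
#' @param planted_log2fc_range magnitude interval for planted log2 fold
#'   changes.
#' @param dispersion NB dispersion phi (> 0); variance = mu + phi mu^2.
#' @param mean_expression_range interval of baseline NB means (counts),
#'   sampled log-uniformly.
#' @param cis_pair_fraction fraction of placeable DE lncRNAs re-placed within
#'   10 kb of a gene that inherits their planted fold change.
#' @param low_coverage_fraction fraction of contigs whose mean coverage falls
#'   below the 50x discovery floor.
#' @param contig_length_range,gene_length_range length intervals (nt / bp).
#' @param efficiency_true qPCR amplification efficiency in (1, 2].
#' @param ct_noise_sd Gaussian technical noise SD on each Ct replicate.
#' @param qpcr_bio_sdlog lognormal sdlog of per-individual biological
#'   variability in the qPCR experiment.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chromosomes = 2L,
                             chrom_length = 300000L,
                             n_genes = 120L,
                             n_coding_contigs = 300L,
                             n_noncoding_contigs = 300L,
                             placeable_fraction = 0.33,
                             n_replicates = 3L,
                             conditions = c("control", "LPS", "polyIC",
                                            "betaglucan"),
                             de_fraction_per_condition = c(LPS = 0.10,
                                                           polyIC = 0.03,
                                                           betaglucan = 0.04),
                             common_de_fraction = 0.02,
                             gene_de_fraction = 0.05,
                             down_fraction = c(LPS = 0.4, polyIC = 0.7,
                                               betaglucan = 0.7),
                             planted_log2fc_range = c(2, 6),
                             dispersion = 0.1,
                             mean_expression_range = c(10, 300),
                             cis_pair_fraction = 0.5,
                             low_coverage_fraction = 0.05,
                             contig_length_range = c(250L, 800L),
                             gene_length_range = c(500L, 3000L),
                             efficiency_true = 2,
                             ct_noise_sd = 0.2,
                             qpcr_bio_sdlog = 0.2) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              n_coding_contigs = as.integer(n_coding_contigs),
              n_noncoding_contigs = as.integer(n_noncoding_contigs),
              placeable_fraction = placeable_fraction,
              n_replicates = as.integer(n_replicates),
              conditions = conditions,
              de_fraction_per_condition = de_fraction_per_condition,
              common_de_fraction = common_de_fraction,
              gene_de_fraction = gene_de_fraction,
              down_fraction = down_fraction,
              planted_log2fc_range = planted_log2fc_range,
              dispersion = dispersion,
              mean_expression_range = mean_expression_range,
              cis_pair_fraction = cis_pair_fraction,
              low_coverage_fraction = low_coverage_fraction,
              contig_length_range = as.integer(contig_length_range),
              gene_length_range = as.integer(gene_length_range),
              efficiency_true = efficiency_true,
              ct_noise_sd = ct_noise_sd,
              qpcr_bio_sdlog = qpcr_bio_sdlog)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  pos <- c("n_chromosomes", "chrom_length", "n_replicates")
  for (f in pos) if (cfg[[f]] <= 0) stop("'", f, "' must be positive")
  nonneg <- c("n_genes", "n_coding_contigs", "n_noncoding_contigs")
  for (f in nonneg) if (cfg[[f]] < 0) stop("'", f, "' must be non-negative")
  props <- c("placeable_fraction", "common_de_fraction", "gene_de_fraction",
             "cis_pair_fraction", "low_coverage_fraction")
  for (f in props) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("'", f, "' must lie in [0, 1]")
  }
  if (any(cfg$de_fraction_per_condition < 0) ||
      sum(cfg$de_fraction_per_condition) + cfg$common_de_fraction > 1) {
    stop("DE fractions must be non-negative and sum to at most 1")
  }
  if (length(cfg$conditions) < 2L || anyDuplicated(cfg$conditions)) {
    stop("conditions must be >= 2 distinct labels")
  }
  if (cfg$conditions[1] != "control" || sum(cfg$conditions == "control") != 1) {
    stop("conditions must contain exactly one 'control' label, first")
  }
  stimuli <- setdiff(cfg$conditions, "control")
  if (!all(stimuli %in% names(cfg$de_fraction_per_condition)) ||
      !all(stimuli %in% names(cfg$down_fraction))) {
    stop("de_fraction_per_condition and down_fraction must name every stimulus")
  }
  if (cfg$dispersion <= 0) stop("dispersion must be > 0")
  if (diff(cfg$planted_log2fc_range) < 0 || cfg$planted_log2fc_range[1] <= 0) {
    stop("planted_log2fc_range must be a positive increasing interval")
  }
  if (cfg$mean_expression_range[1] <= 0 ||
      diff(cfg$mean_expression_range) < 0) {
    stop("mean_expression_range must be a positive increasing interval")
  }
  if (cfg$efficiency_true <= 1 || cfg$efficiency_true > 2) {
    stop("efficiency_true must lie in (1, 2]")
  }
  invisible(cfg)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate the synthetic genome, gene annotation and gene-to-GO map
#'
#' Builds uniform-random chromosome sequences, packs non-overlapping gene
#' intervals with random strands into them (erroring when the requested genes
#' cannot fit), and draws 1-3 GO terms per gene from the miniature GO DAG
#' shipped with the package. Deterministic given the config seed.
#'
#' @param cfg a [synthetic_config()].
#' @return List with `genome` (named `DNAStringSet`), `genes` (`data.frame`:
#'   `gene_id`, `chrom`, `start`, `end` 0-based half-open, `strand`),
#'   `gene2go` (named list) and `dag` (the mini `go_dag`).
#' @export
generate_genome <- function(cfg) {
  validate_synthetic_config(cfg)
  with_seed(child_seed(cfg$seed, 1L), {
    chroms <- setNames(
      vapply(seq_len(cfg$n_chromosomes), function(i) random_dna(cfg$chrom_length),
             character(1)),
      paste0("chr", seq_len(cfg$n_chromosomes)))
    per_chrom <- tabulate(rep_len(seq_len(cfg$n_chromosomes), cfg$n_genes),
                          nbins = cfg$n_chromosomes)
    genes <- list()
    gid <- 0L
    for (ci in seq_len(cfg$n_chromosomes)) {
      ng <- per_chrom[ci]
      if (ng == 0L) next
      lens <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]),
                     ng, replace = TRUE)
      free <- cfg$chrom_length - sum(lens)
      if (free < ng) {
        stop("infeasible packing: ", ng, " genes of total length ", sum(lens),
             " bp do not fit in a ", cfg$chrom_length, " bp chromosome")
      }
      cuts <- sort(runif(ng))
      gaps <- floor(diff(c(0, cuts)) * free)
      starts <- cumsum(gaps) + c(0L, cumsum(lens))[seq_len(ng)]
      for (gi in seq_len(ng)) {
        gid <- gid + 1L
        genes[[gid]] <- data.frame(
          gene_id = sprintf("gene%04d", gid),
          chrom = names(chroms)[ci],
          start = as.integer(starts[gi]),
          end = as.integer(starts[gi] + lens[gi]),
          strand = sample(c("+", "-"), 1),
          stringsAsFactors = FALSE)
      }
    }
    genes <- if (length(genes)) do.call(rbind, genes) else
      data.frame(gene_id = character(), chrom = character(),
                 start = integer(), end = integer(), strand = character(),
                 stringsAsFactors = FALSE)
    dag <- read_obo_subset(system.file("extdata", "go_mini.obo",
                                       package = "lncmine"))
    roots <- c("GO:0008150", "GO:0003674", "GO:0005575")
    pool <- setdiff(dag$terms$id, roots)
    gene2go <- setNames(lapply(seq_len(nrow(genes)), function(i) {
      sort(sample(pool, sample(1:3, 1)))
    }), genes$gene_id)
    list(genome = Biostrings::DNAStringSet(chroms), genes = genes,
         gene2go = gene2go, dag = dag)
  })
}

sample_de_pattern <- function(n, stimuli, excl_fracs, common_frac) {
  cats <- c("none", stimuli, "all")
  probs <- c(1 - sum(excl_fracs) - common_frac, excl_fracs[stimuli],
             common_frac)
  sample(cats, n, replace = TRUE, prob = probs)
}

# lfc matrix (n x stimuli) for given patterns; common patterns share one value
planted_lfc <- function(patterns, stimuli, lfc_range, down_fraction) {
  n <- length(patterns)
  lfc <- matrix(0, n, length(stimuli), dimnames = list(NULL, stimuli))
  for (i in seq_len(n)) {
    p <- patterns[i]
    if (p == "none") next
    targets <- if (p == "all") stimuli else p
    mag <- runif(1, lfc_range[1], lfc_range[2])
    sgn <- if (runif(1) < down_fraction[[targets[1]]]) -1 else 1
    lfc[i, targets] <- sgn * mag
  }
  lfc
}

#' Generate synthetic transcripts, homology hits and the ground truth
#'
#' Coding contigs carry a long (> 200 bp) ORF of codons drawn from a bundled
#' codon-usage table between random UTRs, and are all annotated (each gets
#' strong homology hits). Non-coding contigs are rejection-sampled to have no
#' complete ORF longer than 200 bp; `round(placeable_fraction * n)` of them
#' are copied verbatim from the genome so they can be placed by exact match,
#' and a fraction of the placeable, differentially expressed ones are
#' re-placed within 10 kb of a gene, forming positively coupled cis pairs
#' whose genes inherit the lncRNA's planted fold change. Mean coverage is
#' drawn so that `low_coverage_fraction` of contigs falls below 50.
#'
#' @param cfg a [synthetic_config()].
#' @param genome output of [generate_genome()].
#' @return List with `records` ([transcript_records]), `hits` (homology hit
#'   `data.frame`) and `truth` (a `synthetic_truth`: `contigs`, `genes`,
#'   `cis_pairs` tables).
#' @export
generate_transcripts <- function(cfg, genome) {
  validate_synthetic_config(cfg)
  stimuli <- setdiff(cfg$conditions, "control")
  with_seed(child_seed(cfg$seed, 2L), {
    codon_tab <- read.delim(system.file("extdata", "codon_usage_synthetic.tsv",
                                        package = "lncmine"),
                            stringsAsFactors = FALSE)
    n_cod <- cfg$n_coding_contigs
    n_non <- cfg$n_noncoding_contigs
    ids <- sprintf("contig%05d", seq_len(n_cod + n_non))
    class <- rep(c("coding", "noncoding"), c(n_cod, n_non))

    seqs <- character(n_cod + n_non)
    for (i in seq_len(n_cod)) {
      k <- sample(67:220, 1)
      orf <- paste0("ATG",
                    paste(sample(codon_tab$codon, k, replace = TRUE,
                                 prob = codon_tab$freq), collapse = ""),
                    sample(c("TAA", "TAG", "TGA"), 1))
      seqs[i] <- paste0(random_dna(sample(0:80, 1)), orf,
                        random_dna(sample(0:120, 1)))
    }

    lens <- sample(seq(cfg$contig_length_range[1], cfg$contig_length_range[2]),
                   n_non, replace = TRUE)
    n_place <- round(cfg$placeable_fraction * n_non)
    placeable_idx <- if (n_place > 0) sort(sample(n_non, n_place)) else integer()
    chrom_seqs <- as.character(genome$genome)
    placement <- data.frame(idx = integer(), chrom = character(),
                            start = integer(), end = integer(),
                            strand = character(), stringsAsFactors = FALSE)
    for (j in seq_len(n_non)) {
      L <- lens[j]
      if (j %in% placeable_idx) {
        got <- FALSE
        for (try in seq_len(500L)) {
          ci <- sample(length(chrom_seqs), 1)
          st <- sample.int(nchar(chrom_seqs[ci]) - L + 1L, 1) - 1L
          cand <- substr(chrom_seqs[ci], st + 1L, st + L)
          if (max_orf_ok(cand)) {
            seqs[n_cod + j] <- cand
            placement <- rbind(placement, data.frame(
              idx = j, chrom = names(genome$genome)[ci], start = st,
              end = st + L, strand = "+", stringsAsFactors = FALSE))
            got <- TRUE
            break
          }
        }
        if (!got) {
          stop("rejection sampling exhausted: could not draw a genome window ",
               "of ", L, " nt with longest ORF <= 200 bp")
        }
      } else {
        got <- FALSE
        for (try in seq_len(500L)) {
          cand <- random_dna(L)
          if (max_orf_ok(cand)) { seqs[n_cod + j] <- cand; got <- TRUE; break }
        }
        if (!got) {
          stop("rejection sampling exhausted: could not draw a ", L,
               " nt sequence with longest ORF <= 200 bp")
        }
      }
    }

    n_all <- n_cod + n_non
    lengths_all <- nchar(seqs)
    low <- runif(n_all) < cfg$low_coverage_fraction
    coverage <- ifelse(low, runif(n_all, 5, 49.5),
                       50 + rlnorm(n_all, meanlog = log(250), sdlog = 1))

    patterns <- sample_de_pattern(n_all, stimuli,
                                  cfg$de_fraction_per_condition,
                                  cfg$common_de_fraction)
    lfc <- planted_lfc(patterns, stimuli, cfg$planted_log2fc_range,
                       cfg$down_fraction)
    base_mean <- 10^runif(n_all, log10(cfg$mean_expression_range[1]),
                          log10(cfg$mean_expression_range[2]))

    genes <- genome$genes
    gpatterns <- if (nrow(genes)) {
      scale <- cfg$gene_de_fraction /
        max(1e-12, sum(cfg$de_fraction_per_condition) + cfg$common_de_fraction)
      sample_de_pattern(nrow(genes), stimuli,
                        cfg$de_fraction_per_condition * scale,
                        cfg$common_de_fraction * scale)
    } else {
      character()
    }
    glfc <- planted_lfc(gpatterns, stimuli, cfg$planted_log2fc_range,
                        cfg$down_fraction)
    gene_base <- 10^runif(nrow(genes), log10(cfg$mean_expression_range[1]),
                          log10(cfg$mean_expression_range[2]))

    # cis pairs: placeable DE lncRNAs re-placed within 10 kb of a partner gene
    de_placeable <- placeable_idx[patterns[n_cod + placeable_idx] != "none"]
    n_cis <- round(cfg$cis_pair_fraction * length(de_placeable))
    cis_pairs <- data.frame(lncrna_id = character(), gene_id = character(),
                            sign = integer(), stringsAsFactors = FALSE)
    if (n_cis > 0 && nrow(genes) > 0) {
      chosen <- sort(sample(de_placeable, n_cis))
      partner <- sample(nrow(genes), n_cis)
      for (m in seq_along(chosen)) {
        j <- chosen[m]
        gi <- partner[m]
        L <- lens[j]
        cl <- nchar(chrom_seqs[match(genes$chrom[gi], names(genome$genome))])
        got <- FALSE
        for (try in seq_len(500L)) {
          gap <- sample(0:8000, 1)
          side <- sample(c("left", "right"), 1)
          st <- if (side == "left") genes$start[gi] - gap - L else
            genes$end[gi] + gap
          if (st < 0L || st + L > cl) next
          ci <- match(genes$chrom[gi], names(genome$genome))
          cand <- substr(chrom_seqs[ci], st + 1L, st + L)
          if (max_orf_ok(cand)) {
            seqs[n_cod + j] <- cand
            placement[placement$idx == j,
                      c("chrom", "start", "end")] <-
              list(genes$chrom[gi], as.integer(st), as.integer(st + L))
            got <- TRUE
            break
          }
        }
        if (!got) {
          stop("rejection sampling exhausted: could not place a cis lncRNA ",
               "within 10 kb of ", genes$gene_id[gi])
        }
        gpatterns[gi] <- patterns[n_cod + j]
        glfc[gi, ] <- lfc[n_cod + j, ]
        cis_pairs <- rbind(cis_pairs, data.frame(
          lncrna_id = ids[n_cod + j], gene_id = genes$gene_id[gi],
          sign = 1L, stringsAsFactors = FALSE))
      }
    }

    hits <- synth_hits(ids, class, lengths_all)

    contigs <- data.frame(
      id = ids, class = class, annotated = class == "coding",
      mean_coverage = coverage, length = lengths_all,
      placed = FALSE, chrom = NA_character_, start = NA_integer_,
      end = NA_integer_, strand = NA_character_,
      base_mean = base_mean, pattern = patterns,
      stringsAsFactors = FALSE)
    if (nrow(placement)) {
      rowi <- n_cod + placement$idx
      contigs$placed[rowi] <- TRUE
      contigs$chrom[rowi] <- placement$chrom
      contigs$start[rowi] <- placement$start
      contigs$end[rowi] <- placement$end
      contigs$strand[rowi] <- placement$strand
    }
    for (s in stimuli) {
      contigs[[paste0("lfc_", s)]] <- lfc[, s]
      contigs[[paste0("de_", s)]] <- lfc[, s] != 0
    }
    gene_truth <- genes
    gene_truth$base_mean <- gene_base
    gene_truth$pattern <- gpatterns
    for (s in stimuli) {
      gene_truth[[paste0("lfc_", s)]] <- glfc[, s]
      gene_truth[[paste0("de_", s)]] <- glfc[, s] != 0
    }

    records <- transcript_records(ids, seqs, mean_coverage = coverage,
                                  annotated = class == "coding")
    truth <- structure(list(contigs = contigs, genes = gene_truth,
                            cis_pairs = cis_pairs, stimuli = stimuli),
                       class = "synthetic_truth")
    list(records = records, hits = hits, truth = truth)
  })
}

max_orf_ok <- function(s, max_orf = 200L) {
  o <- find_longest_orf(s)
  is.null(o) || o$length_bp <= max_orf
}

synth_hits <- function(ids, class, lens) {
  rows <- list()
  for (i in seq_along(ids)) {
    if (class[i] == "coding") {
      n_hit <- sample(1:2, 1)
      ev <- 10^-runif(n_hit, 5, 80)
    } else if (runif(1) < 0.1) {
      n_hit <- 1L
      ev <- 10^runif(1, -2.9, 0.9)  # weak hits stay above the 1e-3 threshold
    } else {
      next
    }
    for (h in seq_len(n_hit)) {
      alen <- max(20L, round(lens[i] / 3 * runif(1, 0.4, 0.9)))
      rows[[length(rows) + 1L]] <- data.frame(
        qseqid = ids[i],
        sseqid = sprintf("sp|P%05d|SYN", sample(99999L, 1)),
        pident = round(runif(1, 35, 98), 1), length = alen,
        mismatch = sample(0:30, 1), gapopen = sample(0:4, 1),
        qstart = 1L, qend = min(lens[i], alen * 3L),
        sstart = 1L, send = alen,
        evalue = ev[h], bitscore = round(runif(1, 40, 400), 1),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- as.data.frame(setNames(
      c(list(character(), character()), rep(list(numeric()), 10)),
      .blast_cols))
    return(out)
  }
  do.call(rbind, rows)
}

#' Generate the NB count matrix for contigs and genes
#'
#' Counts for feature i in sample s follow
#' `NB(mean = mu_i * 2^lfc, dispersion = phi)` where the planted log2 fold
#' change applies when the feature is DE in the sample's condition (the
#' control never carries a planted change). Deterministic given the config
#' seed.
#'
#' @param cfg a [synthetic_config()].
#' @param truth the `synthetic_truth` from [generate_transcripts()].
#' @return List with `counts` (integer matrix, features x samples),
#'   `lengths`, `condition` (factor per sample) and `samples`.
#' @export
generate_counts <- function(cfg, truth) {
  validate_synthetic_config(cfg)
  stimuli <- truth$stimuli
  with_seed(child_seed(cfg$seed, 3L), {
    feat <- rbind(
      data.frame(id = truth$contigs$id, base_mean = truth$contigs$base_mean,
                 length = truth$contigs$length,
                 truth$contigs[, paste0("lfc_", stimuli), drop = FALSE],
                 stringsAsFactors = FALSE),
      data.frame(id = truth$genes$gene_id, base_mean = truth$genes$base_mean,
                 length = truth$genes$end - truth$genes$start,
                 truth$genes[, paste0("lfc_", stimuli), drop = FALSE],
                 stringsAsFactors = FALSE))
    condition <- factor(rep(cfg$conditions, each = cfg$n_replicates),
                        levels = cfg$conditions)
    samples <- paste0(rep(cfg$conditions, each = cfg$n_replicates), "_",
                      rep(seq_len(cfg$n_replicates), length(cfg$conditions)))
    counts <- matrix(0L, nrow(feat), length(samples),
                     dimnames = list(feat$id, samples))
    lfc_mat <- vapply(as.character(condition), function(cond) {
      if (cond == "control") rep(0, nrow(feat)) else
        feat[[paste0("lfc_", cond)]]
    }, numeric(nrow(feat)))
    # per-feature RNG substream: a feature's counts depend only on its own
    # mean and planted changes, never on other features' (so a non-DE feature
    # regenerates identically whatever is planted elsewhere)
    base_seed <- child_seed(cfg$seed, 3L)
    for (i in seq_len(nrow(feat))) {
      set.seed((base_seed + 7919L * i) %% 214748329L)
      mu <- feat$base_mean[i] * 2^lfc_mat[i, ]
      counts[i, ] <- if (cfg$dispersion < 1e-12) rpois(length(mu), mu) else
        rnbinom(length(mu), size = 1 / cfg$dispersion, mu = mu)
    }
    storage.mode(counts) <- "integer"
    list(counts = counts, lengths = feat$length, condition = condition,
         samples = samples)
  })
}

#' Generate the qPCR validation arm
#'
#' Selects 12 validation lncRNAs (4 per stimulus, favouring the most highly
#' expressed planted DE non-coding contigs), simulates a new
#' individual-mussel experiment (3 individuals x 4 conditions), and emits a
#' Ct table (`Ct = intercept - log_E(expression) + noise`, technical
#' triplicates) plus a 5-point 5-fold dilution series per assay. The
#' reference gene is non-DE by construction.
#'
#' @param cfg a [synthetic_config()].
#' @param truth the `synthetic_truth`.
#' @return List with `ct` (`data.frame`: `individual`, `condition`, `target`,
#'   `replicate`, `ct`), `dilution` (`data.frame`: `target`, `dilution`,
#'   `replicate`, `ct`), `targets` (`data.frame`: `target`, `stimulus`),
#'   `reference`, `efficiency_true`.
#' @export
generate_qpcr <- function(cfg, truth) {
  validate_synthetic_config(cfg)
  stimuli <- truth$stimuli
  ct_tab <- truth$contigs
  with_seed(child_seed(cfg$seed, 4L), {
    chosen <- character()
    targets <- list()
    for (s in stimuli) {
      cand <- ct_tab[ct_tab$class == "noncoding" &
                       ct_tab[[paste0("de_", s)]] &
                       !(ct_tab$id %in% chosen), , drop = FALSE]
      cand <- cand[order(-cand$base_mean), , drop = FALSE]
      if (nrow(cand) < 4L) {
        stop("fewer than 4 DE lncRNAs available for stimulus ", s)
      }
      pick <- cand$id[1:4]
      chosen <- c(chosen, pick)
      targets[[s]] <- data.frame(target = pick, stimulus = s,
                                 stringsAsFactors = FALSE)
    }
    targets <- do.call(rbind, targets)
    rownames(targets) <- NULL
    ref <- "ref_18S"
    E <- cfg$efficiency_true
    assays <- c(targets$target, ref)
    base <- c(ct_tab$base_mean[match(targets$target, ct_tab$id)], 5e4)
    lfc_mat <- rbind(
      as.matrix(ct_tab[match(targets$target, ct_tab$id),
                       paste0("lfc_", stimuli), drop = FALSE]),
      matrix(0, 1, length(stimuli), dimnames = list(NULL,
                                                    paste0("lfc_", stimuli))))
    intercepts <- runif(length(assays), 33, 37)
    inds <- paste0("ind", seq_len(cfg$n_replicates))
    rows <- list()
    for (a in seq_along(assays)) {
      for (ind in inds) {
        for (cond in cfg$conditions) {
          lfc <- if (cond == "control") 0 else
            lfc_mat[a, paste0("lfc_", cond)]
          expr <- base[a] * 2^lfc * exp(rnorm(1, 0, cfg$qpcr_bio_sdlog))
          ct0 <- intercepts[a] - log(expr) / log(E)
          for (rep_ in 1:3) {
            rows[[length(rows) + 1L]] <- data.frame(
              individual = ind, condition = cond, target = assays[a],
              replicate = rep_, ct = ct0 + rnorm(1, 0, cfg$ct_noise_sd),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    ct <- do.call(rbind, rows)
    dil_rows <- list()
    for (a in seq_along(assays)) {
      b0 <- runif(1, 18, 24)
      for (d in 5^-(0:4)) {
        for (rep_ in 1:3) {
          dil_rows[[length(dil_rows) + 1L]] <- data.frame(
            target = assays[a], dilution = d, replicate = rep_,
            ct = b0 - log(d) / log(E) + rnorm(1, 0, cfg$ct_noise_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
    list(ct = ct, dilution = do.call(rbind, dil_rows), targets = targets,
         reference = ref, efficiency_true = E)
  })
}

#' Run the whole synthetic generator
#'
#' Convenience wrapper calling [generate_genome()], [generate_transcripts()],
#' [generate_counts()] and [generate_qpcr()] in order.
#'
#' @param cfg a [synthetic_config()].
#' @param qpcr also generate the qPCR arm (requires enough planted DE
#'   lncRNAs).
#' @return List with `cfg`, `genome`, `records`, `hits`, `truth`, `counts`,
#'   `qpcr`.
#' @export
simulate_experiment <- function(cfg = synthetic_config(), qpcr = TRUE) {
  genome <- generate_genome(cfg)
  tx <- generate_transcripts(cfg, genome)
  counts <- generate_counts(cfg, tx$truth)
  qp <- if (qpcr) generate_qpcr(cfg, tx$truth) else NULL
  list(cfg = cfg, genome = genome, records = tx$records, hits = tx$hits,
       truth = tx$truth, counts = counts, qpcr = qp)
}

#' Write every synthetic input to disk in its standard format
#'
#' Emits the genome and contigs as FASTA, genes as GFF3, truth placements as
#' BED, coverage / counts / truth / Ct / dilution / gene-to-GO tables as TSV,
#' and a JSON echo of the configuration. All files round-trip through the
#' package's readers.
#'
#' @param sim output of [simulate_experiment()].
#' @param dir output directory (created if missing).
#' @return Named character vector of the written paths.
#' @export
write_synthetic_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(sim$genome$genome, p("genome.fasta"))
  write_contigs(sim$records, p("contigs.fasta"))
  write.table(data.frame(id = sim$records$id,
                         mean_coverage = sim$records$mean_coverage),
              p("coverage.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_blast_hits(sim$hits, p("hits.tsv"))
  genes <- sim$genome$genes
  genes$go <- unname(sim$genome$gene2go[genes$gene_id])
  write_gff3_genes(genes, p("genes.gff3"))
  placed <- sim$truth$contigs[sim$truth$contigs$placed, , drop = FALSE]
  write_bed_placements(
    data.frame(id = placed$id, chrom = placed$chrom, start = placed$start,
               end = placed$end, strand = placed$strand,
               stringsAsFactors = FALSE),
    p("placements.bed"))
  write_matrix_tsv(sim$counts$counts, p("counts.tsv"))
  write.table(data.frame(feature_id = rownames(sim$counts$counts),
                         length = sim$counts$lengths),
              p("feature_lengths.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample = sim$counts$samples,
                         condition = as.character(sim$counts$condition)),
              p("design.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$contigs, p("truth_contigs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$genes[, setdiff(names(sim$truth$genes), "go")],
              p("truth_genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth$cis_pairs, p("truth_cis_pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_gene2go_tsv(sim$genome$gene2go, p("gene2go.tsv"))
  if (!is.null(sim$qpcr)) {
    write.table(sim$qpcr$ct, p("qpcr_ct.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(sim$qpcr$dilution, p("qpcr_dilution.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sim$qpcr$targets, p("qpcr_targets.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(unclass(sim$cfg), p("config.json"), auto_unbox = TRUE,
                       digits = NA)
  out <- list.files(dir, full.names = TRUE)
  setNames(out, basename(out))
}
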
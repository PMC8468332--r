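#' Configuration for an end-to-end pipeline run
#'
#' @param synthetic a [synthetic_config()] driving input generation.
#' @param min_cov coverage floor of the discovery cascade.
#' @param max_orf ORF-length ceiling (bp).
#' @param evalue homology e-value threshold.
#' @param cutoff coding-probability cutoff.
#' @param window cis-neighbour window (bp).
#' @param fc_threshold,fdr_threshold DE gates.
#' @param alpha enrichment significance cutoff.
#' @param run_qpcr toggle for the qPCR validation stage.
#' @param outdir optional directory for artifacts (TSV/JSON); `NULL` keeps
#'   everything in memory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            min_cov = 50, max_orf = 200, evalue = 1e-3,
                            cutoff = 0.5, window = 10000,
                            fc_threshold = 2, fdr_threshold = 0.05,
                            alpha = 0.05, run_qpcr = TRUE, outdir = NULL) {
  thr <- c(min_cov = min_cov, max_orf = max_orf, evalue = evalue,
           cutoff = cutoff, window = window, fc = fc_threshold,
           fdr = fdr_threshold, alpha = alpha)
  if (any(thr[c("min_cov", "max_orf", "window")] < 0) ||
      any(thr[c("evalue", "cutoff", "fc", "fdr", "alpha")] <= 0)) {
    stop("pipeline thresholds must be positive")
  }
  structure(list(synthetic = synthetic, min_cov = min_cov, max_orf = max_orf,
                 evalue = evalue, cutoff = cutoff, window = window,
                 fc_threshold = fc_threshold, fdr_threshold = fdr_threshold,
                 alpha = alpha, run_qpcr = run_qpcr, outdir = outdir),
            class = "pipeline_config")
}

#' Run the full lncRNA analysis pipeline on synthetic data
#'
#' Executes, in order: input generation, coding-model training (on an
#' independently seeded labelled training set from the same generator),
#' discovery cascade, genome placement, 10-kb neighbour extraction,
#' per-stimulus differential expression with Venn partitioning, GO enrichment
#' of the DE-lncRNA neighbour genes, lncRNA-gene correlation, and (optionally)
#' the qPCR validation arm with cross-platform correlation. Every output is
#' reproducible from the configuration seed.
#'
#' @param config a [pipeline_config()].
#' @return A `lnc_pipeline` list with all stage outputs and `report`
#'   (a `lnc_run_report`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- t1 - t0
    t0 <<- t1
  }

  sim <- simulate_experiment(config$synthetic, qpcr = config$run_qpcr)
  tick("synthesis")

  train_cfg <- config$synthetic
  train_cfg$seed <- child_seed(config$synthetic$seed, 99L)
  train_cfg$n_coding_contigs <- max(60L, config$synthetic$n_coding_contigs %/% 2L)
  train_cfg$n_noncoding_contigs <- max(60L, config$synthetic$n_noncoding_contigs %/% 2L)
  train_genome <- generate_genome(train_cfg)
  train_tx <- generate_transcripts(train_cfg, train_genome)
  model <- build_coding_model(train_tx$records,
                              train_tx$truth$contigs$class == "coding",
                              cutoff = config$cutoff)
  tick("model_training")

  casc <- run_cascade(sim$records, sim$hits, model, evalue = config$evalue,
                      min_cov = config$min_cov, max_orf = config$max_orf,
                      cutoff = config$cutoff)
  tick("discovery")

  placed <- place_transcripts(casc$lncrnas, genome = sim$genome$genome)
  tick("placement")

  neighbors <- extract_neighbors(placed$placements, sim$genome$genes,
                                 window = config$window)
  tick("neighbors")

  de <- run_de(sim$counts$counts, sim$counts$lengths, sim$counts$condition,
               control = "control", fc_threshold = config$fc_threshold,
               fdr_threshold = config$fdr_threshold)
  lnc_ids <- casc$lncrnas$id
  de_lnc <- lapply(de$tables, function(tb) tb$id[tb$de_flag & tb$id %in% lnc_ids])
  de_lnc_venn <- venn_partition(de_lnc)
  de_union <- unique(unlist(de_lnc, use.names = FALSE))
  cluster <- if (length(de_union) >= 2L) {
    cluster_heatmap(de$tpm[de_union, , drop = FALSE], sim$counts$condition)
  } else {
    NULL
  }
  tick("differential_expression")

  dag <- sim$genome$dag
  full_map <- propagate_annotations(sim$genome$gene2go, dag)
  background <- sim$genome$genes$gene_id
  neighbor_genes <- lapply(de_lnc, function(ids) {
    unique(neighbors$gene_id[neighbors$lncrna_id %in% ids])
  })
  neighbor_venn <- venn_partition(neighbor_genes)
  enrichment <- lapply(names(neighbor_genes), function(s) {
    study <- neighbor_genes[[s]]
    if (!length(study)) return(NULL)
    res <- fisher_enrichment(study, background, full_map)
    reduce_most_specific(res, dag, alpha = config$alpha)
  })
  names(enrichment) <- names(neighbor_genes)
  tick("enrichment")

  gene_de <- lapply(de$tables, function(tb) {
    tb$id[tb$de_flag & tb$id %in% background]
  })
  lps_links <- correlate_links(de$tpm, neighbors,
                               de_lncrnas = de_lnc[["LPS"]] %||% character(),
                               de_genes = gene_de[["LPS"]] %||% character())
  tick("correlation")

  qpcr <- NULL
  if (config$run_qpcr && !is.null(sim$qpcr)) {
    eff <- vapply(split(sim$qpcr$dilution, sim$qpcr$dilution$target),
                  function(ser) efficiency_from_dilution(ser)$efficiency,
                  numeric(1))
    qfc <- quantify_qpcr(sim$qpcr$ct, eff, ref_gene = sim$qpcr$reference)
    rseq <- do.call(rbind, lapply(names(de$tables), function(s) {
      tb <- de$tables[[s]]
      sel <- sim$qpcr$targets$target[sim$qpcr$targets$stimulus == s]
      data.frame(target = sel, stimulus = s,
                 fc = tb$fc[match(sel, tb$id)], stringsAsFactors = FALSE)
    }))
    qfc <- qfc[paste(qfc$target, qfc$stimulus) %in%
                 paste(rseq$target, rseq$stimulus), , drop = FALSE]
    xcor <- cross_platform_correlation(rseq, qfc)
    qpcr <- list(efficiencies = eff, qpcr_fc = qfc, rnaseq_fc = rseq,
                 cross_platform = xcor)
  }
  tick("qpcr")

  report <- new_run_report(
    seed = config$synthetic$seed,
    thresholds = list(min_cov = config$min_cov, max_orf = config$max_orf,
                      evalue = config$evalue, cutoff = config$cutoff,
                      window = config$window, fc = config$fc_threshold,
                      fdr = config$fdr_threshold, alpha = config$alpha),
    total_contigs = nrow(sim$records),
    putative = nrow(casc$lncrnas),
    placed = nrow(placed$placements),
    de = data.frame(
      stimulus = de$summary$stimulus,
      up = vapply(de$tables, function(tb)
        sum(tb$direction == "up" & tb$id %in% lnc_ids), integer(1)),
      down = vapply(de$tables, function(tb)
        sum(tb$direction == "down" & tb$id %in% lnc_ids), integer(1)),
      total = lengths(de_lnc),
      row.names = NULL, stringsAsFactors = FALSE),
    de_venn = de_lnc_venn,
    neighbor_counts = lengths(neighbor_genes),
    neighbor_venn = neighbor_venn,
    enriched_terms = vapply(enrichment, function(e)
      if (is.null(e)) 0L else sum(e$p < config$alpha), integer(1)),
    correlated_pairs = nrow(lps_links$results),
    cross_platform_r = if (is.null(qpcr)) NA_real_ else qpcr$cross_platform$r,
    timings = unlist(timings))

  out <- list(config = config, sim = sim, model = model, cascade = casc,
              placement = placed, neighbors = neighbors, de = de,
              de_lnc = de_lnc, cluster = cluster, enrichment = enrichment,
              correlation = lps_links, qpcr = qpcr, report = report)
  class(out) <- "lnc_pipeline"
  if (!is.null(config$outdir)) write_pipeline_artifacts(out, config$outdir)
  out
}

new_run_report <- function(...) {
  structure(list(...), class = "lnc_run_report")
}

#' @export
print.lnc_run_report <- function(x, ...) {
  cat("<lnc_run_report>\n")
  cat(sprintf("  contigs: %d; putative lncRNAs: %d (%.2f%%); placed: %d (%.2f%%)\n",
              x$total_contigs, x$putative,
              if (x$total_contigs) 100 * x$putative / x$total_contigs else 0,
              x$placed,
              if (x$putative) 100 * x$placed / x$putative else 0))
  for (i in seq_len(nrow(x$de))) {
    cat(sprintf("  DE lncRNAs %-10s %d (%d up / %d down); neighbour genes: %d\n",
                x$de$stimulus[i], x$de$total[i], x$de$up[i], x$de$down[i],
                x$neighbor_counts[[x$de$stimulus[i]]]))
  }
  if (!is.na(x$cross_platform_r)) {
    cat(sprintf("  qPCR cross-platform log10-FC Pearson r = %.3f\n",
                x$cross_platform_r))
  }
  invisible(x)
}

#' @export
print.lnc_pipeline <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Arithmetic consistency checks of a run report
#'
#' Verifies the internal identities a summary report must satisfy: per
#' stimulus, up + down equals the DE total; Venn partition counts are
#' non-negative, sum to the union and per-set region sums match the set
#' totals; and placed <= putative <= total contigs. Percentages are always
#' recomputed from counts, never stored, so they cannot drift.
#'
#' @param report a `lnc_run_report` (possibly hand-constructed from published
#'   counts).
#' @return `data.frame` of `check`/`pass`; all-pass for a consistent report.
#' @export
report_consistency_check <- function(report) {
  checks <- list()
  add <- function(name, pass) {
    checks[[length(checks) + 1L]] <<- data.frame(check = name, pass = pass,
                                                 stringsAsFactors = FALSE)
  }
  if (!is.null(report$de) && nrow(report$de)) {
    for (i in seq_len(nrow(report$de))) {
      add(paste0("up+down=total[", report$de$stimulus[i], "]"),
          report$de$up[i] + report$de$down[i] == report$de$total[i])
    }
  }
  for (vname in c("de_venn", "neighbor_venn")) {
    v <- report[[vname]]
    if (is.null(v)) next
    add(paste0(vname, ": counts sum to union"),
        sum(v$count) == attr(v, "union_size"))
    labels <- unique(unlist(strsplit(v$region, "&", fixed = TRUE)))
    totals <- report[[sub("_venn", "_set_totals", vname)]]
    if (!is.null(totals)) {
      for (lb in labels) {
        in_lb <- vapply(strsplit(v$region, "&", fixed = TRUE),
                        function(r) lb %in% r, logical(1))
        add(paste0(vname, ": region sums match |", lb, "|"),
            sum(v$count[in_lb]) == totals[[lb]])
      }
    }
  }
  if (!is.null(report$total_contigs)) {
    add("placed <= putative <= total",
        report$placed <= report$putative &&
          report$putative <= report$total_contigs)
  }
  out <- do.call(rbind, checks)
  if (is.null(out)) {
    out <- data.frame(check = character(), pass = logical(),
                      stringsAsFactors = FALSE)
  }
  out
}

write_pipeline_artifacts <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_synthetic_inputs(x$sim, file.path(dir, "inputs"))
  write_contigs(x$cascade$lncrnas, p("putative_lncrnas.fasta"))
  write.table(x$cascade$report$stages, p("cascade_stages.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(x$placement$placements)) {
    write_bed_placements(x$placement$placements, p("lncrna_placements.bed"))
  }
  write.table(x$neighbors, p("neighbor_links.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (s in names(x$de$tables)) {
    write.table(x$de$tables[[s]], p(paste0("de_", s, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(regions = as.list(setNames(x$report$de_venn$count,
                                    x$report$de_venn$region))),
    p("de_venn.json"), auto_unbox = TRUE, digits = NA)
  write.table(x$correlation$results, p("lps_correlations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rep_json <- x$report
  rep_json$de_venn <- as.list(setNames(x$report$de_venn$count,
                                       x$report$de_venn$region))
  rep_json$neighbor_venn <- as.list(setNames(x$report$neighbor_venn$count,
                                             x$report$neighbor_venn$region))
  jsonlite::write_json(unclass(rep_json), p("run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
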
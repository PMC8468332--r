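# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small but DE-rich so the 12-lncRNA qPCR arm is selectable at this scale.
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(seed = 1L, n_chromosomes = 2L, chrom_length = 80000L,
         n_genes = 40L, n_coding_contigs = 60L, n_noncoding_contigs = 60L,
         de_fraction_per_condition = c(LPS = 0.2, polyIC = 0.12,
                                       betaglucan = 0.12),
         common_de_fraction = 0.06),
    list(...))
  do.call(synthetic_config, args)
}

small_sim <- function() cached("small_sim", simulate_experiment(small_cfg()))

default_sim <- function() {
  cached("default_sim", simulate_experiment(synthetic_config(seed = 1L)))
}

# Coding model trained on an independently seeded set, as the pipeline does.
default_model <- function() {
  cached("default_model", {
    cfg <- synthetic_config(seed = 1L)
    tcfg <- cfg
    tcfg$seed <- 424243L
    tcfg$n_coding_contigs <- 150L
    tcfg$n_noncoding_contigs <- 150L
    g <- generate_genome(tcfg)
    tx <- generate_transcripts(tcfg, g)
    suppressWarnings(
      build_coding_model(tx$records, tx$truth$contigs$class == "coding"))
  })
}

small_pipeline <- function() {
  cached("small_pipeline", suppressWarnings(
    run_pipeline(pipeline_config(synthetic = small_cfg()))))
}
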
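# lncmine

Discovery and functional profiling of long non-coding RNAs (lncRNAs) in
bulk RNA-Seq of immune-stimulated invertebrate cells, modelled on a
PAMP-challenge experiment in mussel hemocytes: four conditions (control,
LPS, poly I:C, β-glucans) with three biological replicates each.

The package is aimed at transcriptomics practitioners who assemble
contigs de novo (no reliable genome annotation), need to sieve out
putative lncRNAs, and want the downstream statistics — differential
expression, cis-neighbour analysis, GO enrichment, expression
correlation and qPCR validation — in one tested, reproducible toolchain.
Because the motivating kind of dataset is only available as raw reads
plus printed summary tables, the package ships a synthetic-data
generator with known ground truth that emulates the whole experiment,
so every stage can be exercised and benchmarked end to end.

## What it computes

**Discovery cascade.** Starting from assembled contigs (all ≥ 200 nt),
four filters are applied in order:

1. drop contigs with a homology hit at *e* < 10⁻³ (annotated ⇒ not a lncRNA);
2. drop contigs with mean coverage < 50;
3. drop contigs whose longest complete ORF (ATG→stop, six frames) exceeds 200 bp;
4. drop contigs the coding-potential classifier scores ≥ 0.5.

The classifier is a logistic model on four features per transcript —
longest-ORF length, ORF coverage, the Fickett TESTCODE statistic, and
hexamer usage bias (mean in-frame log F_coding(h)/F_noncoding(h)) —
trained on labelled sequences, in the manner of CPAT.

**Genome context.** Surviving lncRNAs are placed on a genome (exact
match, or precomputed BED/minimal-SAM alignments); protein-coding genes
within a 10-kb window (boundary inclusive) are linked as putative
cis-regulatory neighbours, and neighbour sets are Venn-partitioned
across stimuli.

**Differential expression.** Per stimulus vs control: library sizes are
equalised to the geometric mean, a common negative-binomial dispersion
φ is estimated by conditional maximum likelihood (qCML), each feature is
tested with the conditional NB exact test (two-sided by probability
mass), p-values are Benjamini–Hochberg adjusted within the contrast,
and features with |FC| > 2 (fold change on mean TPM + 1) and FDR < 0.05
are flagged. DE lncRNAs are clustered on per-condition mean TPM with
1 − Pearson distance and centroid linkage.

**Enrichment, correlation, validation.** Neighbour genes of DE lncRNAs
are tested for GO over-representation (one-sided hypergeometric) with
reduction to most-specific terms; DE lncRNA / DE neighbour-gene pairs
are correlated (Pearson and Spearman) across all 12 samples; and a
simulated individual-animal qPCR arm (12 lncRNAs, 4 per stimulus) is
quantified by the Pfaffl method — ratio = E_t^ΔCt_t / E_ref^ΔCt_ref with
efficiencies from the CT-slope method, E = 10^(−1/slope) — and compared
with RNA-Seq fold changes by Pearson correlation of log₁₀ FC.

## Worked example

```r
library(lncmine)
res <- run_pipeline(pipeline_config())   # default synthetic study, seed 1
res$report
```

```
<lnc_run_report>
  contigs: 600; putative lncRNAs: 288 (48.00%); placed: 95 (32.99%)
  DE lncRNAs LPS        226 (22 up / 204 down); neighbour genes: 112
  DE lncRNAs polyIC     10 (5 up / 5 down); neighbour genes: 10
  DE lncRNAs betaglucan 13 (3 up / 10 down); neighbour genes: 8
  qPCR cross-platform log10-FC Pearson r = 0.975
```

Reading the report: of 600 synthetic contigs (half coding, half not),
288 survive the cascade — on this small, half-noncoding universe that is
48%, against ~9% on a real assembly where coding and rRNA contigs
dominate. 33% of putative lncRNAs place on the genome (the generator's
planted placeable fraction). LPS drives by far the largest expression
response; the many "down" calls are the compositional echo of strong
planted up-regulation under library-size equalisation (see the
vignette). The qPCR arm, simulated as a separate individual-animal
experiment, reproduces the RNA-Seq fold changes with r = 0.975 across
the 12 validation lncRNAs.

```r
res$cascade$report
```

```
<cascade_report> lncRNA discovery cascade
  input                         600 (100.00%)
  annotation_filter             300 (50.00%)
  coverage_filter               290 (48.33%)
  orf_filter                    290 (48.33%)
  coding_potential_filter       288 (48.00%)
```

Individual stages are exported (`filter_annotated()`,
`filter_coverage()`, `find_longest_orf()`, `fickett_score()`,
`hexamer_bias()`, `train_coding_model()`, `exact_test()`,
`estimate_common_dispersion()`, `extract_neighbors()`,
`fisher_enrichment()`, `cor_pearson()`, `efficiency_from_dilution()`,
`pfaffl_ratio()`, …) and operate on plain data frames and matrices, so
any stage can be run on real inputs (FASTA, BLAST tabular, GFF3, BED,
minimal SAM, count TSVs) via the `read_*` helpers.

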
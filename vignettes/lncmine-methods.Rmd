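---
title: "Methods: lncRNA mining and PAMP-response analysis with lncmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA mining and PAMP-response analysis with lncmine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

lncmine implements a complete bulk-RNA-Seq lncRNA analysis for a
four-condition immune-stimulation design (control, LPS, poly I:C,
β-glucans; three biological replicates each, twelve samples): discovery
of putative lncRNAs from assembled contigs, genome placement with 10-kb
cis-neighbour extraction, negative-binomial exact-test differential
expression, GO enrichment of neighbour genes, lncRNA–gene expression
correlation, and qPCR cross-platform validation. Everything upstream of
assembled contigs (read trimming, de novo assembly, read-to-genome
alignment) is out of scope: contigs, coverage values, homology hits and
counts enter as files.

# The discovery cascade

A transcript qualifies as a putative lncRNA when it survives four
independent predicates, applied in a fixed order so each stage's
attrition is reportable:

1. **Annotation.** Any homology hit with e-value `< 1e-3` marks a
   contig as protein-associated and removes it. The boundary e-value
   itself is kept (the threshold is strict "below").
2. **Coverage.** `mean_coverage < 50` removes a contig; exactly 50 is
   kept. Low-coverage contigs are too unreliable for expression work.
3. **ORF length.** The longest *complete* ORF — ATG to in-frame stop,
   stop included in the length, scanned over all six frames — must not
   exceed 200 bp; a 200-bp ORF or no complete ORF at all is kept. We
   require both start and stop inside the contig: it is the common
   coding-potential convention and gives an unambiguous boundary.
   Six frames are scanned because de novo contigs are unoriented.
   Codons containing N break an ORF (no reported ORF spans an
   ambiguous codon); ties on length go to the forward strand, then the
   smallest start.
4. **Coding potential.** A logistic model on four features — ORF length,
   ORF coverage (ORF/transcript length), the Fickett TESTCODE score and
   hexamer usage bias — scores each contig; scores at or above the
   cutoff (default 0.5; no published operating point exists, so the
   natural probability midpoint is used, configurable) are removed.

Because the four predicates are independent per contig, the staged
output provably equals the intersection of the per-stage keep-sets; the
test suite asserts this, along with monotonicity in the coverage and
ORF thresholds.

The Fickett statistic uses the classic position/content lookup tables
(shipped as R constants) with the `max/(min + 1)` position smoothing;
N bases count nowhere. Hexamer bias is the mean of
`log(F_coding(h)/F_noncoding(h))` over in-frame hexamers (step 3 inside
the longest ORF; whole sequence in frame 0 when no ORF exists), with
both tables pseudocount-smoothed over all 4096 hexamers; hexamers
containing N are skipped. The logistic model is fitted by IRLS
(`stats::glm`, tolerance 1e-8, ≤ 100 iterations) on internally
standardised features; standardisation uses the population SD so the
fit is invariant to duplicating training rows. Under perfect separation
— common with cleanly separable training sets — the fit falls back to a
small ridge penalty (λ = 1e-3) with a warning, which stabilises the
coefficients without moving the decision boundary materially. A
held-out Youden-J cutoff is available but off by default. The model is
always trained on user-provided labelled data; no pretrained
(human- or mollusc-specific) model is bundled, since hexamer
composition is taxon-specific.

# Genome context

Internally every interval is 0-based half-open; conversions happen only
at file boundaries (GFF3 1-based closed, BED 0-based half-open, SAM
1-based), delegated to rtracklayer. Placement keeps at most one locus
per transcript (longest alignment, then first chromosome, lowest
start); in synthetic mode placement is exact-substring search, which is
what makes the planted placeable fraction exactly recoverable.

Neighbour extraction links a placed lncRNA to every gene on the same
chromosome whose interval intersects the lncRNA interval widened by the
window (default 10,000 bp, read as "up to 10 kb" inclusive: a gap of
exactly 10,000 bp still links). The link is strand-agnostic — cis
regulation is not strand-restricted — with the relation (upstream /
downstream / overlapping) reported relative to the lncRNA orientation.
Venn partitioning of 1–3 labelled sets returns all `2^k − 1` disjoint
regions; disjointness and union conservation are asserted on every
call.

# Differential expression

The test is the conditional negative-binomial exact test with a single
common dispersion:

* **Library equalisation.** Columns are scaled to the geometric-mean
  library size with half-to-even rounding. The original exact-test
  formulation used quantile adjustment; plain scaling is a simpler
  deterministic surrogate that preserves zeros exactly and changes
  group sums by at most rounding.
* **Dispersion.** The common φ maximises the summed conditional
  log-likelihood (each feature's within-group counts conditioned on
  their group total, which cancels the per-feature means) over
  φ ∈ [1e-6, 10] via `stats::optimize` at tolerance 1e-6. Simulations
  in the test suite recover φ = 0.2 within [0.15, 0.25] at 2000
  features, 3 + 3 replicates, and drive φ̂ to the lower boundary on
  Poisson data.
* **Exact test.** With equal library sizes the group sums are NB with
  size `n_g/φ`; conditioning on the total `t`, the two-sided p-value
  sums the conditional probabilities of all splits no more probable
  than the observed one (ties within a relative 1e-12 count in). The
  whole conditional pmf is enumerated in log space — exact for every
  `t` that occurs at this package's scale. φ = 0 reduces to the
  conditional binomial test; `t = 0` gives p = 1. The implementation is
  checked against full-enumeration oracles and, independently, against
  edgeR's small-p exact test to 1e-10.
* **Gates.** BH adjustment (the field-default FDR procedure; the
  analysis names only "FDR") within each stimulus-vs-control contrast
  separately, mirroring three independent runs; fold change is computed
  on group mean TPM with a pseudo-TPM of 1 added to both means (zero
  handling is otherwise undefined), reported signed
  (`ratio` or `−1/ratio`); DE requires |FC| > 2 and FDR < 0.05.

DE lncRNAs are clustered on per-condition mean TPM with distance
`1 − Pearson r` and the Lance–Williams centroid update, ties broken
deterministically toward the smallest original feature index;
zero-variance rows get the maximal distance 2 with a warning. The
merge sequence is verified against `stats::hclust(method = "centroid")`
on tie-free data.

**Compositional caveat.** TPM and equalised counts are compositional:
when one stimulus carries strong, mostly one-sided planted
up-regulation (the LPS default), unchanged features are pushed slightly
"down", and with enough samples some cross the gates. This is faithful
to how exact-test pipelines without compositional normalisation (TMM
and relatives are deliberately out of scope) behave on strongly
modulated libraries, and it is why the end-to-end synthetic run calls
more nominal "down" lncRNAs than were planted. The null-data
simulations — where no composition shift exists — show the test itself
holds its size (false-positive fraction ≤ 0.07 at the default gates;
null p-values pass a KS uniformity check at α = 0.01).

# Enrichment

GO annotations are propagated to all is_a ancestors (true-path rule;
the reader accepts an OBO subset with id/name/namespace/is_a only).
Enrichment is the one-sided hypergeometric upper tail per term present
in the study set — over-representation only, matching the "enriched"
reading — against a background defaulting to all annotated genes. No
multiple-testing correction is applied by default (a plain p < 0.05
cutoff is the stated operating point; a BH option exists). Among
significant terms, a term is *most specific* iff none of its
descendants is significant; the up-to-20 most enriched most-specific
biological-process terms are selected. Pathway over-representation
needs no extra machinery: the same function accepts any gene→term map
without a DAG.

# Correlation and qPCR validation

Pearson r uses the two-sided t transform `t = r√((n−2)/(1−r²))`;
Spearman is Pearson on midranks with the same transform (an exact
permutation p is available for n ≤ 10). Zero-variance vectors yield an
explicitly flagged undefined result. Pair selection is the neighbour-
link-restricted cross product of DE lncRNAs × DE genes, correlated
across all 12 samples; "significant correlation" means p < 0.05,
two-sided, uncorrected.

Amplification efficiency comes from the CT-slope method: technical
replicates are averaged per dilution point (arithmetic mean of Ct —
the natural scale for a log-linear quantity), mean Ct is regressed on
log10(dilution), and `E = 10^(−1/slope)`; estimates outside (1, 2.2]
or with non-negative slope are flagged rather than discarded. Relative
expression is the Pfaffl ratio `E_t^ΔCt_t / E_ref^ΔCt_ref` with
ΔCt = Ct(control) − Ct(treated) per individual against its own control
well; per-target ratios are combined as geometric means (ratios are
multiplicative) and reported as signed fold changes, with `−k ↔ 1/k`
as the documented conversion so cross-platform comparison can take
log10.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions every recovery benchmark runs under.

* **Genome.** Uniform-random chromosomes (default 2 × 300 kb) with
  non-overlapping genes (default 120, lengths 0.5–3 kb) packed by
  stick-breaking; 1–3 GO terms per gene drawn from a miniature GO DAG
  shipped as a plain-text OBO subset.
* **Transcripts.** 300 coding contigs (random UTRs around an ORF of
  67–220 codons sampled from a bundled codon-usage table — biased the
  way real coding sequence is) and 300 non-coding contigs (250–800 nt,
  rejection-sampled to carry no complete ORF > 200 bp; a retry budget
  turns pathological configurations into explicit errors). All coding
  contigs get strong homology hits (annotated); 10% of non-coding
  contigs get weak hits above the e-value threshold, exercising the
  threshold semantics. `round(0.33 × n)` non-coding contigs are copied
  verbatim from the genome (placeable), the default matching the ~⅓
  genome-placement rate such assemblies achieve in practice.
* **Coverage.** Log-normal (50 + lognormal(log 250, 1)) with a 5%
  mixture below the 50× floor. The coverage law of real contigs is not
  documented anywhere usable, so this is a free modelling choice:
  log-normal is the standard shape for coverage, and the below-floor
  fraction is kept small so the floor removes few true lncRNAs.
* **Planted expression.** Baseline NB means log-uniform on [10, 300];
  dispersion φ = 0.1 (BCV ≈ 0.32, appropriate for pooled-hemocyte
  biological triplicates); planted |log2 FC| uniform on [2, 6] — the
  scale of immune-stimulation responses; LPS carries the largest DE
  fraction (10% exclusive, vs 3% poly I:C, 4% β-glucans, 2% common to
  all three with a shared fold change, mostly down-regulated for the
  two non-LPS stimuli). The control never carries a planted change.
  Counts are drawn NB(μ·2^lfc, φ) with a per-feature RNG substream, so
  a non-DE feature regenerates identically whatever is planted
  elsewhere — that independence is itself a tested contract.
* **Cis pairs.** Half of the placeable, DE lncRNAs are re-placed within
  10 kb of a partner gene, which inherits the lncRNA's planted fold
  change (positive coupling). Pair coordinates are brute-force verified
  against the 10-kb rule in the tests.
* **qPCR.** A separate simulated individual-animal experiment:
  `Ct = intercept − log_E(expression) + N(0, 0.2)` in technical
  triplicate, per-individual lognormal biological noise (sdlog 0.2,
  individuals being noisier than pooled wells), true efficiency 2.0,
  a 5-point 5-fold dilution series per assay, and a high-abundance
  non-DE reference gene. The 12 validation targets are the most highly
  expressed planted-DE lncRNAs, four per stimulus — mirroring how
  robust candidates are chosen for validation.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: read-level error and mapping ambiguity
(placement is exact), paralogous collapse, fragmented or chimeric
contigs, GC and length biases in counting, tag-wise dispersion
heterogeneity, compositional normalisation issues beyond those induced
by planted DE, genuine GO signal (term assignment is random, so
enrichment machinery is verified by closed forms and oracles, not by
planted enriched terms), and trans-acting regulation.

# Numerical and design notes

* One master seed; each stage derives a child seed by a fixed affine
  map kept below 2³¹, and generators save/restore the global RNG state,
  so they are pure functions of (config, seed).
* Benchmarks in tests and the acceptance script use 600 contigs,
  120 genes, 2000-feature DE simulations and a 500 × 500 neighbour
  oracle — sizes chosen so the whole suite re-derives every oracle in a
  few minutes while keeping every estimate stable across seeds.
* The permutation-null check for cis-pair correlation is scoped to
  condition-exclusive pairs: a pair planted DE in all three stimuli
  keeps a 9-of-12 "high column" overlap under any column permutation,
  so label permutation cannot (and should not) null it out.
* `venn_partition` always materialises all `2^k − 1` regions, including
  empty ones, so downstream arithmetic never special-cases absent
  regions.
* Report percentages are recomputed from counts at print time, never
  stored, making the printed-summary identities structural.

# Limitations

The exact test uses a single common dispersion (no tag-wise
moderation), equalisation is plain scaling (no TMM/quantile options),
enrichment understands is_a edges only, and the discovery classifier is
only as good as its training labels — on real data one would train on
curated coding/non-coding sets from a related taxon. Numerical equality
with any specific published DE list is not a goal: those depend on
proprietary assembly and testing internals and on raw data external to
this package.
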
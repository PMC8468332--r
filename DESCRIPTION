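Package: lncmine
Title: Long Non-Coding RNA Mining and PAMP-Response Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovery of putative long non-coding RNAs (lncRNAs) from
    assembled transcriptome contigs by a filtering cascade (homology,
    coverage, ORF length and a re-implemented coding-potential classifier
    combining Fickett TESTCODE, hexamer usage bias and ORF features in a
    logistic model), genome placement with 10-kb cis-neighbour gene
    extraction, negative-binomial exact-test differential expression with
    conditional maximum-likelihood common dispersion, Venn partitioning,
    GO Fisher enrichment with reduction to most specific terms,
    lncRNA-gene expression correlation, and qPCR validation via the CT
    slope efficiency method and Pfaffl relative quantification. Includes
    a synthetic-data generator with known ground truth that emulates the
    statistical structure of a PAMP-stimulation RNA-Seq experiment in
    mussel hemocytes (control, LPS, poly I:C, beta-glucans; three
    replicates each).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
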
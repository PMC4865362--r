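Package: hydroxymeta
Title: Spike-In Calibrated TAB-Seq Quantification of 5-Hydroxymethylcytosine
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for TET-assisted bisulfite sequencing (TAB-seq)
    of 5-hydroxymethylcytosine (5hmC). Reads per-cytosine call tables,
    estimates bisulfite non-conversion and beta-glucosyltransferase protection
    rates from fully-5mC lambda and fully-5hmC pUC19 spike-in controls,
    computes raw and protection-scaled global %5hmCG per sample, stratifies
    genes into expression quintiles after exon-length normalisation, builds
    strand-aware metagene profiles of weighted 5hmCG levels over upstream,
    gene-body and downstream bins, compares samples with a chi-square test on
    pooled counts, and checks robustness to sequencing depth by binomial
    subsampling. Includes a seeded synthetic-data generator with known truth
    for every estimator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
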
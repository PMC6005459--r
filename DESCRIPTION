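Package: epitrio
Title: Biallelic Tumour-Suppressor Inactivation Analysis from Paired
    Tumour/Normal Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for establishing biallelic inactivation of a tumour
    suppressor gene from desk-scale sequencing evidence, organised as three
    analysis strands. (1) B-allele-fraction analysis of paired tumour/normal
    small-variant tables: heterozygous-site filtering, mirrored-BAF and
    depth-ratio tracks, hidden-Markov segmentation into neutral, copy-neutral
    LOH, loss and gain states, contiguous LOH-run detection, and a fractional
    copy-number aberration score. (2) Targeted bisulfite-amplicon analysis:
    per-read per-CpG methylation calling, per-site methylation proportions,
    classification of reads into densely methylated versus unmethylated
    epialleles with Wilson confidence intervals, mutation allele fractions
    from local sequence context, and mosaic cell-fraction estimation.
    (3) Expression-subtype analysis: variance filtering, average-linkage
    hierarchical clustering, an empirical-Bayes moderated-t differential
    expression test with Benjamini-Hochberg correction, cross-cohort signature
    overlap, and SVD metagene scoring of developmental-stage marker gene sets.
    A synthetic-data module generates truth-known inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ape,
    vcfR,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
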
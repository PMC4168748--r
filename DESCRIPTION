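Package: cloneSNV
Title: Somatic SNV Discovery from Clone Sanger Sequencing of the hnRNP A1
    M9 Amplicon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for clone-based somatic single nucleotide
    variant (SNV) analysis of the hnRNP A1 exon 8-9 amplicon: per-clone
    variant calling by global alignment, HGVS genomic/cDNA/protein
    annotation, functional-domain and PY-NLS epitope classification,
    novelty classification against local variant catalogs, per-cohort
    somatic SNV rates compared against a polymerase error model,
    QuikChange-style mutagenic primer design with the manufacturer melting
    temperature formula, cross-species conservation reports, and a
    constraint-driven synthetic data generator (reference amplicon, clone
    simulator, catalog stand-ins, ortholog fixtures).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    BiocGenerics,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
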
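Package: admixscan
Title: Ancestry-Aware Association Mapping and Selection Scans in Admixed
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting admixed livestock genomes with per-allele
    local-ancestry calls. Implements crossover-based dating of admixture
    (recent-crossover counting and filtering of recently admixed animals),
    VanRaden genomic relationship matrices with leave-one-chromosome-out
    support and PCA of population structure, a single-SNP mixed-model
    genome-wide association that jointly estimates the ancestral-origin
    allele effect and the residual SNP allele effect under repeated records,
    within-population (EHH/iHS) and between-population (EHHS/iES/Rsb)
    haplotype-homozygosity selection scans, Storey-Tibshirani q-values, and
    seed-and-extend candidate-region calling with ancestry tracking. A
    forward-in-time simulator of admixed cohorts with known ancestry tracts,
    injectable selective sweeps and repeated-record phenotypes makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    withr
Suggests:
    VariantAnnotation,
    SummarizedExperiment,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
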
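Package: tilingsweep
Title: Tiling-Array Population Genomics: SFP Calling, CNV Segmentation,
    Association Mapping and Haplotype-Sharing Sweep Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for population-genomic analysis of tiling
    microarray hybridisation data. Calls single feature polymorphisms (SFPs)
    from log2 fold changes against a reference accession with ROC-based
    threshold calibration, segments deletions and duplications as probe
    runs, tests feature-class and gene-family enrichment against a
    length-proportional null, maps marker-trait associations with a general
    linear model that controls for population structure via admixture
    covariates (empirical p-values, FDR estimation, least-squares means),
    annotates associations with metabolic pathways and minimum reaction
    paths, and scans for selective sweeps with the pairwise haplotype
    sharing (PHS) statistic standardised within allele-frequency classes.
    Ships a synthetic-data generator that emulates the statistical
    structure of a 54-accession Arabidopsis thaliana tiling-array study so
    the full pipeline is testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    GenomeInfoDb,
    igraph,
    geosphere,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    emmeans
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
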
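Package: XYscan
Title: Detection and Characterization of Young Sex Chromosomes from
    Population Genomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Windowed population-genetic scans (Hudson's F_ST, nucleotide
    diversity, absolute and net divergence, Tajima's D), genotype-pattern
    evidence for heterogametic sex chromosomes (XY-patterned sites,
    per-individual and windowed inbreeding coefficients, PCA, Ajk
    relatedness), sex-differential sequencing-coverage analysis,
    alignment-free k-mer discovery of Y- and X-linked sequence, and
    quartet topology weighting. Includes a coalescent-based synthetic-data
    generator that simulates populations carrying a young XX-XY region,
    so every stage of the pipeline can be validated by parameter-recovery
    experiments without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    jsonlite,
    matrixStats,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
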
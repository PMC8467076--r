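Package: emscreen
Title: Analysis of EMS Mutagenesis Screens in Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for ethyl methanesulfonate (EMS)
    forward-genetics screens in haploid bacteria. Reads per-mutant variant
    call tables (Snippy-style TSV or VCF) against a single reference,
    classifies the mutation spectrum (G:C->A:T transition signature),
    scores SNP clustering along the genome with a proximity-weighted
    sliding window, calls and annotates mutation hotspots, computes
    strand-aware codon changes, and analyses the screen's phenotype
    assays: four-parameter-logistic reporter kinetics with maximal-slope
    extraction, genetic-linkage filtering, and transformation-frequency
    statistics with detection-limit handling. A synthetic-data generator
    emulates a high-GC bacterial genome and every assay input so the full
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    vcfR,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
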
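Package: m5Cmap
Title: Mapping and Interpreting NSUN6-Dependent m5C Sites in mRNA
Version: 0.1.0
Authors@R:
    person("m5Cmap", "Maintainers", email = "m5cmap@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for locating and interpreting
    NSUN6-dependent 5-methylcytosine (m5C) sites in mRNA. Implements
    miCLIP truncation-site calling (barcode demultiplexing, PCR
    deduplication, cytosine assignment within 2 nt, RPM normalization and
    a replicate-consensus filter), conversion-aware bisulfite alignment
    and capped site-level methylation quantification, ribosome-profiling
    periodicity and codon-occupancy analysis, coverage matrices and
    occupancy classification around sites, a translation-efficiency
    differential statistic with FDR control, Fisher odds-ratio overlap
    tests, and motif/hairpin/readthrough sequence analyses. Ships a
    synthetic-data generator with planted ground truth so every stage can
    be validated end-to-end at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
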
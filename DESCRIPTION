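Package: methwindow
Title: Whole-Genome Bisulfite Sequencing Differential Methylation and
    Critical-Window Gene Classification
Version: 0.1.0
Authors@R:
    person("Methwindow", "Developers", email = "methwindow@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully testable reimplementation of a whole-genome
    bisulfite sequencing (WGBS) differential-methylation workflow: a seeded
    synthetic-data generator (toy genome with CpG islands, cohort design with
    age, estradiol treatment and library-kit batch structure, planted
    methylation effects, and simulated bisulfite reads), strand-aware
    CpG/CHG/CHH context classification, a lone-cytosine bisulfite-conversion
    read filter, per-site methylation calling, covariate-adjusted binomial
    logistic-regression differential testing with hyper/hypo classification,
    promoter/exon/intron/intergenic and CpG island/shore/shelf annotation,
    per-gene directional responsiveness calls with a critical-window filter
    across age groups, and hypergeometric gene-set over-representation with
    Benjamini-Hochberg adjustment. A pipeline runner and command-line
    interface orchestrate the stages and emit a machine-readable run report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    methods,
    withr,
    optparse,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
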
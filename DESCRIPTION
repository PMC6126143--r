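Package: dualTax
Title: Dual-Database Taxonomy Assignment for 16S rRNA Amplicon Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns taxonomy to 16S rRNA gene amplicon sequences by leveraging
    a small, curated ecosystem-specific reference database together with a large
    comprehensive one. Query sequences are routed to the ecosystem-specific
    database only when their best full-length recalculated percent identity
    against its references meets a user-chosen cutoff; both groups are then
    classified with an 8-mer naive Bayesian classifier with bootstrap
    confidence and recombined. Includes BLAST tabular (outfmt 6) post-processing,
    the full-length percent identity recalculation, hit-rank agreement and
    coarse-rank conflict diagnostics, percent-classified and taxonomic-richness
    metrics, a percent identity cutoff sweep, in-silico primer trimming, and a
    seeded synthetic-community generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
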
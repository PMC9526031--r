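Package: dietbarcodeR
Title: Fecal DNA Metabarcoding Diet Analysis: Curation, Profiling and
    Community Statistics
Version: 0.1.0
Authors@R:
    person("IVP", "Pipeline Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a fecal DNA-metabarcoding diet
    analysis workflow for a wild primate population: demultiplexing of tagged
    amplicon reads, a multi-stage OTU-table curation cascade (length and
    minimum-count filters, abundance-based denoising, 97% greedy clustering,
    cascading local-then-global taxonomic assignment, geographic range rules,
    contaminant and tag-jump filtering, replicate-consensus aggregation),
    relative read abundance diet profiles aggregated by month, season and
    individual, permutation-based community statistics (Bray-Curtis, PCoA,
    ANOSIM, Mantel, indicator value analysis, Shannon diversity with the
    Hutcheson t-test), read-accounting reports, and a synthetic-data
    generator with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
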
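Package: brainrelz
Title: Region-Relative Expression Z-Scores Across Human Neurodevelopment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for region-relative gene expression across
    human brain development. Computes per-specimen z-scores of cerebellar
    expression relative to all other sampled grey-matter regions from
    BrainSpan-style RPKM matrices, fits two-phase (prenatal/postnatal)
    age trajectories by Pearson correlation, benchmarks a target gene
    against the genome-wide z-score distribution per specimen, builds
    positively and negatively correlated gene sets, and tests annotation
    terms for over- and under-representation with an exact hypergeometric
    test and Benjamini-Hochberg FDR control. Includes a synthetic-data
    generator that emulates the BrainSpan developmental transcriptome
    with planted trajectories, co-expression modules and enriched terms,
    so the whole pipeline is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
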
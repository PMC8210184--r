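Package: apmsdecon
Title: Comparative Interactome Deconvolution for AP-MS and ChIP-MS Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative bait-prey interactome analysis from affinity
    purification and chromatin immunoprecipitation mass spectrometry (AP-MS /
    ChIP-MS) intensity tables: mock (no-antibody) background subtraction,
    contaminant-repository frequency filtering, replicate-averaged log2
    fold-change quantification of prey response to bait-expression modulation
    with two-way ANOVA and concordance classification, multi-bait Venn set
    algebra assigning proteins to canonical / non-canonical / catalytic
    complex-membership categories, and overlap statistics (hypergeometric and
    Fisher exact tests with Benjamini-Hochberg correction) against reference
    gene and protein lists. Includes a synthetic-data generator that emulates
    the full pull-down replicate design with planted complexes, contaminants,
    dropout and modulation effects, so every pipeline stage can be scored
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
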
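Package: mossdiv
Title: Multi-Scale Diversity Analysis of Moss Communities in Paired
    Exclosure Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hierarchically sampled bryophyte abundance
    data from paired herbivore-exclosure experiments. Provides alpha
    diversity (richness, log-variance evenness, bias-corrected inverse
    Simpson), abundance-based Bray-Curtis beta diversity partitioned into
    balanced-variation (turnover) and abundance-gradient (nestedness)
    components, species contributions to beta diversity (SCBD), the
    variance-ratio test of overall interspecific association with its
    chi-square criterion, pairwise Spearman association screening,
    PERMANOVA and stratified paired permutation contrasts, growth-form
    summaries, and a hierarchical synthetic-data generator emulating a
    paired exclosure/control design with nested quadrats and cells.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
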
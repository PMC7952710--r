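Package: pddkit
Title: Pattern Discovery and Disentanglement for Mixed-Mode Relational Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics-driven, fully interpretable pattern mining for
    mixed-mode relational tables and aligned-sequence blocks. Builds the
    matrix of adjusted standardized residuals over all attribute-value
    pairs, disentangles it by eigendecomposition into statistical source
    spaces, grows statistically significant high-order patterns inside
    each disentangled unit, and assembles a two-level knowledge base
    linking sources, patterns and entities. The knowledge base supports
    entity clustering, outlier and mislabel detection, and pattern-based
    supervised classification, with a synthetic-data generator that
    plants entangled multi-source ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    mclust,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
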
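Package: atlasmapr
Title: Quantitative Projection of Query Metacells onto Annotated
    Single-Cell Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects a query single-cell RNA-seq dataset, represented as
    metacells, onto an annotated reference metacell atlas. Each query
    metacell is modelled as a convex mixture of atlas metacells by
    simplex-constrained least squares on log expression; per-gene
    multiplicative technology biases are inferred and corrected,
    incompatible genes are filtered by expression range and by per-type
    fold skew, metacells that cannot be explained by a single atlas
    region are tested as two-region composites (doublet-like states),
    and per-metacell / per-gene quality annotations are produced.
    Includes a seeded synthetic fixture generator with known ground
    truth (mixture weights, technology biases, held-out novel types,
    doublets) for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    Matrix,
    methods,
    purrr,
    quadprog,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
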
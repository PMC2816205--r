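Package: coexpred
Title: Co-Expression Neighbor Models for Cross-Strain Gene Expression
    Prediction
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the held-out expression of target genes in one
    yeast strain from complete time-course data in other strains, using
    co-expression neighborhoods: standard k-nearest-neighbor averaging,
    a mutual nearest neighbor variant with adaptive neighborhood sizes,
    a dense-subnetwork neighborhood, and a per-timepoint linear
    regression on the same gene's profiles in the complete strains.
    Includes the rank-based challenge evaluation (Spearman/Pearson
    gene- and time-profile accuracies, exact and asymptotic one-sided
    p-values, overall significance score), random-gene holdout model
    selection with a k sweep, and a synthetic multi-strain time-course
    generator with planted co-expression modules for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
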
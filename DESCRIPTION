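Package: glottodiv
Title: Linking Structural Linguistic Diversity and Genetic Diversity on
    Geodesic Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating cell-wise structural linguistic diversity
    (posterior normalized Shannon entropy of feature states from hierarchical
    spatial models) and cell-wise genetic diversity (hierarchically smoothed
    Wright's inbreeding coefficient F), and for relating the two through a
    measurement-error hierarchical regression with correlated random slopes,
    tensor-product spatial smooths, and approximate leave-one-out model
    comparison. Includes an icosahedral geodesic hexagonal grid builder with
    equal-earth projection, a synthetic-world generator with known ground
    truth for end-to-end validation, Gibbs samplers for the Gaussian and
    Polya-Gamma-augmented logistic hierarchical models, and Pareto-smoothed
    importance-sampling leave-one-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    splines,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
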
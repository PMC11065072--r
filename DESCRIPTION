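Package: comorbidRx
Title: Drug Repurposing from Mendelian Disease Comorbidity
Version: 0.1.0
Authors@R:
    person("comorbidRx", "authors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Recommends candidate drugs for complex diseases by linking
    Mendelian disease comorbidity to druggable causal genes, and evaluates
    the recommendations with covariate-adjusted logistic regression,
    degree-preserving permutation nulls, per-disease and per-gene
    druggability prioritization, and Mendelian-cancer genetic similarity
    (driver gene overlap and tissue co-expression). Includes a synthetic
    data generator with planted effects so the whole pipeline is testable
    without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
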
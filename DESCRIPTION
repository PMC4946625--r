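Package: netincon
Title: Loop Inconsistency and the Design-by-Treatment Interaction Model
    for Network Meta-Analysis
Version: 0.1.0
Authors@R: person("netincon", "developers", role = c("aut", "cre"),
    email = "netincon@example.org")
Description: Tools for studying inconsistency in network meta-analysis
    through the algebra of consistency partitions. Constructs Lu-Ades
    loop inconsistency models from treatment orderings, computes unions
    of inconsistency models as common refinements of partitions, and
    verifies computationally that the union of all loop inconsistency
    models is the design-by-treatment interaction model. Builds
    contrast-level design matrices for consistency, loop, and
    design-by-treatment interaction models, fits them by generalized
    least squares with an exchangeable heterogeneity structure, and
    performs the global Wald chi-square test for inconsistency. Includes
    a simulator for contrast-level network meta-analysis data with
    controlled heterogeneity and design-level inconsistency.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
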
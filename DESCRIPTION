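Package: availmdr
Title: Case-Control SNP Association and Available-Case Multifactor
    Dimensionality Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Association analysis for case-control studies of categorical
    genetic and environmental risk factors, built around tobacco-related
    multiple primary neoplasm cohorts.  Provides per-SNP odds ratios under
    heterozygous, extreme and dominant collapse models with exact p-values,
    Hardy-Weinberg equilibrium tests, EM-based pairwise linkage
    disequilibrium, and an "Available" multifactor dimensionality reduction
    (MDR) engine with status-stratified cross-validation, cross-validation
    consistency, shuffled-repeat averaging and OR-MDR cell-level effect
    sizes.  Includes a penetrance-model case-control simulator and fixtures
    reconstructed from published genotype count tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
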
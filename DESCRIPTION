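Package: coexmod
Title: Weighted Gene Co-Expression Modules in Paired Two-Arm Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of whole-blood leukocyte transcriptome
    responses in paired pre/post designs with two treatment arms, as in
    human endotoxemia studies of TNF-alpha antagonism. Provides detection
    filtering, k-nearest-neighbour imputation and variance-stabilizing
    (affine + generalized-log) normalization; paired differential
    expression with Benjamini-Hochberg control and a nested-linear-model
    ANOVA for treatment-responsive probes; weighted co-expression network
    construction (soft-thresholded Pearson adjacency, topological overlap,
    average-linkage clustering with an adaptive tree cut); module
    eigengenes, module membership, module-level treatment tests with
    Bonferroni control, hub genes and direction counts; hypergeometric
    over-representation against user-supplied gene sets; Cytoscape-ready
    network export; and a synthetic-data generator with planted modules
    and ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, tools, graphics, grDevices
Suggests: testthat (>= 3.0.0), mclust, withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
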
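Package: nichedyn
Title: Range and Climatic Niche Shift Dynamics from Two-Period Occurrence Grids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies geographic range shifts and climatic niche shifts of
    species between two survey periods. Builds availability-corrected kernel
    density surfaces of occurrences in geographic space and in a shared
    PCA climate space, computes Schoener's D overlap and the standardized
    unfilling/stability/expansion partition (with analogue-climate handling,
    niche abandonment and pioneering), runs translation-based null-model
    similarity tests, applies niche coverage/breadth filters, and fits
    phylogenetic regressions (Pagel's lambda) of the dynamics metrics on
    species traits. Includes a virtual-species simulator (two-period climate
    grids, Gaussian suitability occupancy with dispersal limitation,
    extinction debt and detection noise, Brownian-motion traits on a
    pure-birth phylogeny) so the full workflow is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
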
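Package: slitmorph
Title: Morphometry of Podocyte Filtration Slits in Two-Channel
    Super-Resolution Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies tight-junction protein recruitment to podocyte
    filtration slits from two-channel (nephrin / claudin-5)
    super-resolution fluorescence z-stacks. Implements the CLDN5/nephrin
    positive-area ratio, skeleton-based filtration slit density (FSD =
    slit length per area), a rule-based foot-process effacement phase
    classifier, and the rank-based cohort statistics (Mann-Whitney U,
    Spearman correlation) that link them. Includes a synthetic
    slit-field generator with vector-level ground truth emulating
    meandering versus linearized filtration slits across an effacement
    continuum, plus TIFF/ROI/CSV input-output and an end-to-end
    reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
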
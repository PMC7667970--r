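Package: mucometry
Title: Quantification of Intestinal Mucus Barrier Function from Bead-Probed Confocal Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the penetrability, thickness and growth rate of
    the intestinal mucus layer from microbead-probed measurements. Implements
    the normalized-penetrability statistic (area under the max-normalized,
    mucus-surface-aligned, cropped frequency curve of tissue-to-bead z-axis
    distances), bead-derived mucus thickness, and ex vivo mucus growth-rate
    estimation from repeated micromanipulator thickness measurements, together
    with the cohort statistics used alongside them (HOMA-IR, normality-gated
    two-group tests and correlations). A fully ground-truthed synthetic-data
    generator emulates two-channel confocal z-stacks of calcein-stained tissue
    overlaid by a mucus layer seeded with 1-micron beads, thickness time
    series, and lean/obese or normoglycemic/diabetic mouse cohorts, so every
    stage of the pipeline can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
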
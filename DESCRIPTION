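Package: flysla
Title: Spontaneous Locomotor Activity, Densitometry and Brain ROI
    Quantification for Single-Fly Arena Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies Drosophila spontaneous locomotor activity from
    single-fly arena recordings: threshold-and-weighted-centroid tracking,
    one-second speed quantization with a 1 mm/s rest/run rule, run-bout
    segmentation, the five standard locomotor parameters plus a
    centrophobia index, and nonparametric group comparison by the
    two-tailed Mann-Whitney U test with significance tiers. Also provides
    dot-blot densitometry (spot optical density, three normalization
    schemes, serial-dilution standard curve, antibody-specificity delta)
    and the pedunculus ROI-ratio statistic R = x/y for confocal brain
    stacks. A synthetic-data module generates ground-truthed two-state
    Markov walker trajectories, rendered arena frames, dot-blot membrane
    phantoms and brain phantoms so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ggplot2,
    jsonlite,
    yaml,
    png,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
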
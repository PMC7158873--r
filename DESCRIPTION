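Package: ortract
Title: Optic Radiation Tract Maps, Microstructure and Resection Disconnection Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative assessment of surgical disconnection of the optic
    radiations from multi-shell diffusion MRI. Builds seed, target and
    exclusion regions from a cortical/subcortical parcellation, filters
    streamline sets by region membership, rasterizes them to visitation maps
    and computes tract-weighted averages of diffusion tensor (FA, MD, AD, RD)
    and spherical mean technique (Long, Trans, microscopic FA and MD,
    orientation dispersion entropy) scalar maps. Scores the cross-sectional
    overlap between a pre-surgical tract map and a resection mask after
    rotating the tract's principal axis to the anterior-posterior direction,
    fits the associated linear mixed-effects group model, and summarizes
    clinical concordance between overlap and visual-field outcome. A synthetic
    cohort module generates every input with known ground truth: tube phantoms
    with an anterior bend, ellipsoidal resection masks, Watson-dispersed
    multi-shell signals with Rician noise, and cohort tables with planted
    effects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    tibble,
    dplyr,
    tidyr,
    rlang,
    lme4,
    lmerTest,
    pracma,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
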
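Package: octgeostat
Title: Geostatistical Texture Analysis of SD-OCT Retinal Layer Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds retinal topographic thickness maps (total retina,
    neurosensory retina, RPE-drusen complex) and an en-face reflectance
    projection of the RPE border from segmented SD-OCT layer boundaries,
    describes their spatial texture with directional empirical semivariogram
    and semimadogram curves under lag, angular and bandwidth tolerances, and
    classifies age-related macular degeneration against control eyes with a
    support vector machine evaluated by repeated stratified k-fold
    cross-validation (sensitivity, specificity, accuracy, AUROC, Cohen's
    kappa).  Includes a synthetic cohort generator with foveal pit, smooth
    layer thickness fields and drusen modelled as localized RPE-border
    elevations, so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
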
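Package: canopyx
Title: Canopy Phenotyping Indices and Trial Statistics for UAV and Ground Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-throughput field phenotyping of cereal trials from
    ground and UAV imagery. Computes RGB colour-space vegetation indices
    (per-image colour components, Green Area, Greener Green Area and the Crop
    Senescence Index), twelve multispectral reflectance indices from 11-band
    stacks, canopy temperature summaries from raw thermal counts,
    nitrogen-use-efficiency metrics, and the trial-level statistical layer
    (ANOVA with Tukey letter groupings, PCA, thresholded correlation networks,
    stepwise yield-model selection with LMG variance decomposition). Includes a
    synthetic-trial generator with known ground truth so every stage of the
    pipeline is testable end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    png,
    tiff
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
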
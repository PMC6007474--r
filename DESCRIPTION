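Package: gliomaquant
Title: Image Quantification and Drug-Synergy Analysis for Glioblastoma Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipelines for glioblastoma cell-culture experiments:
    nuclear-versus-cytoplasmic immunofluorescence intensity measurement from
    DAPI/phalloidin/marker channels; senescence-associated beta-galactosidase
    (SAbGal) positive-area scoring of RGB brightfield images by HSV hue-window
    thresholding; automated neurosphere detection and sizing in stitched
    whole-well brightfield images via illumination correction, contrast
    enhancement, local-entropy detection and watershed separation; and
    Bliss-style projected-additive classification of two-agent drug
    interactions from plate-reader viability tables. A synthetic-data module
    generates images and viability tables with exact ground truth so every
    stage is verifiable without raw microscopy data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    withr,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
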
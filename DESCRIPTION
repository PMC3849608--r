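Package: her2quant
Title: Digital Quantification of HER2 Membrane Immunohistochemistry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies HER2 membrane staining per cell from brightfield
    RGB images of DAB/hematoxylin stained tissue. Separates stains by
    colour deconvolution in optical-density space, detects nuclei on the
    hematoxylin channel, traces membrane mid-lines with an intensity-based
    spot-linking (watershed) algorithm, classifies each cell on the
    four-tier 0/1+/2+/3+ scale from membrane intensity and circumferential
    completeness, and aggregates per-region Field Scores, H-Scores,
    proportional scores and per-class membrane mask areas. Includes the
    companion agreement statistics (Cohen's kappa, quadratic weighted
    kappa, Landis-Koch interpretation, Spearman correlation with Fisher-z
    intervals, two-group feature comparison) and a synthetic brightfield
    tile generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    data.table,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
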
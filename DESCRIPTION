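Package: sheetclust
Title: Quantification of Membrane Protein Cluster Organization on Membrane Sheets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis and spatial-statistics toolkit for quantifying the
    mesoscale organization of membrane proteins (such as the SNAREs syntaxin 1A
    and SNAP25) on glass-adhered plasma membrane sheets. Provides membrane-sheet
    segmentation by blur-and-threshold masking, intensity maxima detection with
    prominence control, per-maximum size estimation by dual-orientation linescan
    Gaussian fitting with quality-control rejection, clustering-degree (rSDM) and
    Pearson colocalization metrics with a flipped-channel chance control,
    nearest-neighbour and pair-distribution statistics against a matched-density
    complete-spatial-randomness (ideal gas) reference, per-sheet intensity
    regression with slope comparison, and a ground-truth synthetic scene
    generator with PSF rendering, photon noise, and fluorophore self-quenching /
    epitope-shielding distortion models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    minpack.lm,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
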
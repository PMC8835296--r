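Package: plaquevol
Title: Automated Volumetric Quantification of Pleural Plaques on Chest CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated volumetric quantification of pleural plaques on
    chest CT. Provides thin maximum-intensity-projection (MIP) slab
    preprocessing, a from-scratch 2D U-Net semantic segmentation network
    trained with a combined binary cross-entropy and Dice loss, Hounsfield-unit
    thresholding to isolate calcified plaque, millilitre volumetrics on both
    native slices and MIP slabs, longitudinal volume-progression analysis, and
    the full similarity/concordance evaluation protocol (pooled Dice, balanced
    accuracy, precision, recall, Lin's concordance correlation coefficient,
    Bland-Altman limits of agreement, Spearman correlation with visual extent
    scores, paired Wilcoxon signed-rank tests). A synthetic thorax phantom
    generator with exact ground-truth masks makes the whole pipeline testable
    end-to-end without any clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
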
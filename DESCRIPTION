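Package: petseg
Title: Inter-Observer Variability of PET Bulky-Tumor Segmentation Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Headless re-implementation of a four-strategy FDG-PET
    bulky-tumor delineation study: percent-of-maximum interactive
    thresholding, gradient-assisted thresholding, manual boundary editing,
    and selection among four established threshold-based algorithms (41%
    SUVmax, SUV 4, SUV 2.5, and a contrast-adapted method based on SUVpeak
    with local background correction).  Synthetic FDG-PET phantoms with
    known ground truth stand in for patient scans, and parameterised
    stochastic observers stand in for human raters.  The evaluation
    framework covers majority-vote reference construction, Jaccard,
    sensitivity and positive predictive value, SUV and total-lesion-glycolysis
    feature differences, and nonparametric multiple-comparison statistics
    (Kruskal-Wallis, Wilcoxon signed-rank, Benjamini-Hochberg).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
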
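Package: liverroi
Title: Automated Liver Attenuation Measurement and Hepatic Steatosis
    Categorization on Unenhanced Chest CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for fully automated measurement of liver attenuation on
    unenhanced chest CT volumes given a binary liver segmentation. Implements
    three Hounsfield-unit estimators (whole-volume mean, largest-axial-slice
    mean, and a parenchymal estimator that places circular 2 cm^2 regions of
    interest near the lateral liver margin on the three largest axial slices),
    a 40 HU threshold classifier for moderate-to-severe hepatic steatosis,
    segmentation accuracy metrics (Dice, Jaccard, Hausdorff and average
    symmetric surface distance), and an agreement-statistics layer
    (Kolmogorov-Smirnov, Bland-Altman limits of agreement, ICC(2,1), MAE/MSE,
    Spearman correlation, and bootstrapped classification performance). A
    synthetic ellipsoid liver phantom generator with embedded vessel tubes
    provides ground truth for validation without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
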
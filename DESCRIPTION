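Package: nsnct
Title: Quantitative CT Analysis of Nonsolid Pulmonary Nodules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-dimensional quantitative analysis of persistent nonsolid
    pulmonary nodules (pure ground-glass nodules) on thin-section chest CT.
    Implements fixed-threshold (-800 HU) segmentation inside a polygonal
    region of interest, twelve densitometric and shape features of the
    largest nodule cross-section (Feret diameters, perimeter, area,
    attenuation statistics, linear mass density, histogram skewness and
    kurtosis, circularity, solidity), mass-doubling-time growth scoring on
    linear mass density, and the associated statistical chain (intraclass
    correlation reliability, Spearman correlation, Mann-Whitney tests,
    univariate and backward-stepwise logistic regression, ROC analysis with
    Youden-optimal cutoffs).  A synthetic CT generator produces single
    slices, baseline/follow-up pairs and whole cohorts with known ground
    truth so that every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
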
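Package: PeakFDR
Title: Topological False Discovery Rate Control for Statistical Parametric Maps
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Random-field-theory inference on the topological features of 3D
    statistical parametric maps (SPMs). Provides Euler characteristic
    densities for Gaussian and t fields, uncorrected and family-wise-error
    corrected p-values for local maxima, conditional cluster-extent
    p-values, and Benjamini-Hochberg false discovery rate control applied
    to peaks, clusters or voxels, with q-values for each feature. Includes
    a Monte-Carlo harness that simulates smooth noise plus randomly placed
    smooth activations, t-transforms the volumes, and evaluates competing
    thresholding procedures by their sensitivity and by the distribution of
    distances between discovered and true peaks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: StatisticalMethod, MultipleComparison, Visualization
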
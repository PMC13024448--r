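Package: myostrain
Title: Myocardial Strain from Cine CMR via Spatiotemporal Displacement Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantification of left-ventricular myocardial strain from
    short-axis cine cardiac MRI. Provides a synthetic deforming-annulus phantom with
    analytic ground-truth displacement and strain, invertible affine normalization of
    displacement fields, two spatiotemporal encoder-decoder regression networks
    (MyoNet and ResMyoNet) with alternating spatial/temporal kernels trained under a
    combined MSE + smooth-L1 + foreground-masked loss, Lagrangian Green-Lagrange
    strain computation with AHA six-segment averaging, and a method-agreement suite
    (SSIM, RMSE, endpoint error, ICC(2,1), Pearson, coefficient of variation,
    Bland-Altman, paired t-tests with Bonferroni correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
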
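Package: itvrange
Title: Range-Dependent Evaluation of Internal Target Volume Delineation
    Strategies for Stereotactic Lung Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital respiratory phantom and four-dimensional computed
    tomography (4DCT) acquisition model for comparing internal target volume
    (ITV) delineation strategies in stereotactic body radiotherapy of lung
    lesions. Simulates a high-contrast spherical target undergoing sinusoidal
    superior-inferior motion, ten-bin respiratory phase sorting with residual
    intra-bin motion, a free-breathing helical snapshot exhibiting interplay
    artifacts, and maximum/average intensity projections. Planning target
    volumes are built from the ten-phase gold standard and four alternative
    strategies (free breathing, augmented free breathing, average and maximum
    intensity projection) using margin-based morphological expansion, and
    compared with the Dice similarity coefficient and planning-target-volume
    ratios across motion ranges. Includes a packaged 17-patient lung SBRT
    cohort table and the summary statistics computed from it.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
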
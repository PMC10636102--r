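Package: TMTmorph
Title: Automated Temporalis Muscle Morphometry and Growth Charts from Brain MRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Measures temporalis muscle thickness (TMT) and cross-sectional
    area from T1-weighted brain MRI. Implements the full measurement pipeline:
    deterministic image preprocessing (isotropic resampling, z-score
    normalisation, median filtering, Otsu background removal, intensity
    standardisation), regression-based localisation of the superior-orbital-roof
    axial slice from maximum-intensity-projection slabs, bilateral muscle
    segmentation with overlapping-tile majority voting and a focal Tversky
    training loss, and thickness quantification as the minimum Feret diameter
    via rotating calipers. Sex-specific LMS (Box-Cox Cole-Green) growth
    centile curves are fitted to cohort measurements by maximum likelihood
    with BIC model selection, with value/centile conversion, leave-one-study-out
    checks and centile-precision propagation. Synthetic head phantoms with
    known muscle thickness and cohorts drawn from known LMS curves support
    end-to-end validation. Agreement statistics (Dice, median absolute error,
    Gwet AC1) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    splines,
    tools,
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Segmentation, Preprocessing, Visualization
RoxygenNote: 7.3.3
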
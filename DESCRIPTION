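Package: ctstrain
Title: Longitudinal Strain and Wall-Motion Classification from Cine Cardiac CT Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures left-ventricular longitudinal strain from time-resolved
    (cine) cardiac CT blood-pool segmentations. Label volumes are resliced
    along 2-, 3- and 4-chamber long-axis planes, the LV endocardial contour is
    extracted with the mitral-valve segment removed, and its length is
    measured by three methods: the raw pixel-chain perimeter, a convex-hull
    corrected perimeter that bridges papillary-muscle indentations, and a
    natural-spline smoothed perimeter that suppresses endocardial surface
    texture. Per-view strain feeds ROC-derived cutoffs for wall-motion
    abnormality classification at the view and patient level, with the
    accompanying agreement and comparison statistics. A synthetic contracting
    left-heart phantom with analytic ground truth supports validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
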
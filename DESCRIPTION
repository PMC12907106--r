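Package: choroborder
Title: Agreement Analysis of Choroidal Tumor Border Annotations Across
    Imaging Modalities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies agreement between expert delineations of choroidal
    tumor (nevus and melanoma) borders drawn on different fundus imaging
    modalities. Contour annotations from color fundus photography and
    scanning laser ophthalmoscopy are coregistered into a common
    millimetre reference frame via anatomical landmarks (least-squares
    similarity transform), cropped to the largest field of view common to
    all modalities, and compared with a multimodal consensus using the
    95th-percentile Hausdorff distance (HD95), the full Hausdorff
    distance, and the Dice overlap coefficient. Summary tables (medians,
    interquartile ranges, counts above a clinical 2 mm acceptability
    threshold), paired Wilcoxon signed-rank comparisons, and univariable
    Gaussian generalized estimating equations with patient-clustered
    sandwich errors relate disagreement to lesion characteristics such as
    pigmentation. A synthetic-cohort generator emulating the lesion,
    grader, and noise structure of such studies makes every pipeline
    stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    polyclip,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    png,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
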
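Package: fwdetect
Title: Video-Based Detection of Unilateral Facial Weakness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the presence and laterality of unilateral facial
    weakness (a cardinal stroke sign) from short videos of a smiling face.
    Each frame is normalized by similarity alignment of 68 facial landmarks
    to a template, described by histograms of oriented gradients (HoG),
    reduced by principal components retaining 95 percent of variance, and
    classified by penalized linear discriminant analysis into normal, left
    or right weakness; a plurality vote over frames yields the per-video
    call. Includes the matching clinical evaluation toolkit (majority-vote
    ground truth from Likert ratings, laterality-aware sensitivity and
    specificity, stratified patient-level bootstrap confidence intervals,
    Fisher's exact test, Fleiss' kappa, subject-grouped cross-validation,
    ROC curves) and a parametric smiling-face video generator with
    analytically known landmarks for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    MASS,
    pROC
Config/testthat/edition: 3
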
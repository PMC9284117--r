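# fwdetect

Video-based detection of unilateral facial weakness — a cardinal stroke
sign — from short clips of a person smiling, together with the
diagnostic-accuracy statistics used to evaluate such detectors against
human raters.

## Who this is for

Researchers building or evaluating automated stroke-sign screening:
the package provides (a) the full classification chain from frames to a
per-video call in {normal, left weakness, right weakness}, (b) the
clinical evaluation toolkit (majority-vote reference standard from Likert
ratings, laterality-aware sensitivity/specificity, patient-level bootstrap
CIs, Fisher's exact test, Fleiss' kappa, ROC), and (c) a parametric
smiling-face video generator with analytically known landmarks, so the
entire chain is testable and reproducible without any external data.

## The method

For a video of a smiling face, per frame:

1. **68 facial landmarks** (standard ordering; pluggable detector backend,
   with explicit exclusion accounting for detection failures);
2. **similarity-transform normalization**: the closed-form least-squares
   transform `x ↦ s R x + t` (scale `s`, rotation `R` with `det R = +1` —
   reflections are forbidden so laterality is never flipped) aligning the
   landmarks to a generalized-Procrustes template fitted on training data;
   the identical transform warps the pixels;
3. **HoG descriptor**: 9 unsigned orientation bins, 8×8-px cells,
   overlapping 2×2-cell L2-Hys blocks;
4. **PCA** retaining 95% of training variance;
5. **penalized LDA**: directions solve `S_b w = μ (S_w + λI) w`; frames are
   classified to the nearest class centroid in discriminant space;
6. **plurality vote** over frame calls gives the video call, with vote
   fractions exposed for ROC analysis.

Evaluation follows diagnostic-accuracy conventions with a laterality-aware
twist: a truth-present video called absent *or called with the wrong side*
is a false negative; sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
with 95% CIs from a 10,000-replicate bootstrap resampling *subjects*
(stratified into weak/normal strata) rather than videos.

## Worked example

```r
library(fwdetect)

# a 20-video cohort: 10 normal, 5 left-weak, 5 right-weak subjects,
# severity 0.6-0.9, hand-held-style jitter
co <- generate_cohort(10, 5, 5, severity_range = c(0.6, 0.9), seed = 11,
                      n_frames_range = c(12, 20), jitter = default_jitter())

# train on the cohort, classify a fresh video
pipe <- train_pipeline(co$videos, lambda = "auto")
v <- generate_face_video(face_params("left", 0.8, n_frames = 16, seed = 99,
                                     jitter = default_jitter()))
classify_video(v, pipe)[c("class", "fractions")]
#> $class
#> [1] "left"
#>
#> $fractions
#> normal   left  right
#> 0.0625 0.8750 0.0625
```

The call is the plurality over per-frame pLDA decisions; `fractions` are
the frame-vote shares (14 of 16 frames voted "left"; the near-neutral
opening frames account for the rest). Subject-grouped
5-fold cross-validation with bootstrap CIs:

```r
res <- run_pipeline(run_config(seed = 1, n_normal = 10, n_left = 5,
                               n_right = 5, n_frames_range = c(12, 20),
                               folds = 5, n_boot = 2000))
res$metrics$accuracy
#> $point
#> [1] 95
#>
#> $lower
#> [1] 85
#>
#> $upper
#> [1] 100
#>
#> $n_boot
#> [1] 2000
res$roc$auc
#> [1] 1
```

i.e. 95% pooled accuracy (19/20 held-out videos correct) with a
stratified patient-level bootstrap 95% CI of 85–100%. Evaluating human
raters from a ratings table instead:

```r
cc <- collapse_ratings(ratings)      # 1-5 Likert -> absent/indet/present
truth <- majority_truth(cc)          # modal call + modal laterality
m <- metrics(confusion(rater_calls, truth))
fleiss_kappa(rating_matrix)          # chance-corrected agreement
```

A thin CLI over the same functions lives at `inst/cli/fwdetect.R`
(`simulate`, `crossval`, `truth`, `evaluate`, `roc` subcommands).

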
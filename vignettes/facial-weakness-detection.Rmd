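---
title: "Detecting unilateral facial weakness from smile videos: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting unilateral facial weakness from smile videos: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fwdetect)
```

## The problem

Unilateral facial weakness — one side of the face failing to contract — is a
cardinal sign of stroke, yet prehospital providers miss or over-call it at
high rates and inter-rater agreement on the facial-palsy item of standard
stroke scales is poor. `fwdetect` implements a video-based detector of the
presence *and* laterality of facial weakness in a short clip of a person
smiling, together with the statistical toolkit needed to evaluate such a
detector the way diagnostic-accuracy studies are evaluated: against a
majority-vote expert reference standard, with laterality-aware error
definitions, patient-level bootstrap confidence intervals, and agreement
statistics.

## The classification chain

Each video is decomposed into frames, and each frame passes through:

1. **Landmarks.** 68 facial landmarks per frame, in the standard ordering
   (jaw 1–17, brows 18–27, nose 28–36, eyes 37–48, mouth 49–68). Landmarks
   come from a pluggable backend: the synthetic backend passes through the
   generator's analytic landmarks, while `extract_landmarks(backend =
   "external")` accepts any user-supplied detector function (e.g. an
   ensemble-of-regression-trees model). A detection failure is an explicit
   signal, never a silent drop: videos whose frames all fail are excluded
   and the exclusion is reported, so *videos in = videos classified +
   videos excluded* always holds.
2. **Normalization.** The least-squares similarity transform (4 dof: scale,
   rotation, translation; closed form via the SVD of the centred
   cross-covariance) maps the frame's landmarks onto a template, and the
   identical transform warps the pixels (inverse-mapped bilinear sampling,
   out-of-frame pixels filled with 0). The rotation determinant is
   constrained positive: a reflection would silently swap the patient's
   left and right, which is one of the output classes. The template is the
   generalized Procrustes mean of the *training* landmarks only, rescaled
   so the RMS landmark distance from the centroid is 0.26 of the
   128-px normalized frame (matching the generator's face framing).
3. **HoG descriptor.** 9 unsigned orientation bins over [0°, 180°), 8×8-px
   cells, 2×2-cell blocks. Gradients are plain central differences
   (one-sided at borders), each pixel splits its gradient magnitude
   linearly between the two adjacent orientation bins, and cells use hard
   spatial assignment — so before normalization, total histogram mass
   equals total gradient magnitude, a property the tests assert. Blocks
   overlap with stride one cell and are L2-Hys normalized (L2, clip at
   0.2, renormalize). Block stride and the normalization scheme are
   exposed in `hog_config()`.
4. **PCA.** Components are fitted by SVD of the centred training matrix
   only; the smallest number of components whose cumulative explained
   variance reaches 95% is kept. Test frames are centred with the
   *training* mean — a leakage test asserts this.
5. **Penalized LDA.** The discriminant directions solve the generalized
   eigenproblem of between-class scatter against the ridge-penalized
   within-class scatter `Sw + λI`, keeping the top `n_classes − 1`
   directions; frames are classified to the nearest class centroid in
   discriminant space.
6. **Voting.** The per-video call is the plurality class over frame calls,
   with the vote fractions exposed (the abnormal-vote fraction is the
   score used for ROC curves).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `variance_target` | 0.95 | PCA retained-variance fraction |
| `lambda` | `"auto"` | ridge penalty on within-class scatter; `"auto"` selects over `{1e-4, 1e-2, 1, 10} × mean(diag(Sw))` by inner 3-fold CV |
| `out_size` | 128 px | normalized face size (multiple of the 8-px cell) |
| `hog_config()` | see above | orientation bins, cell/block geometry, block norm |
| `norm_eps` | 0.5 | block-normalization regularizer (below) |
| `k` | 5 | cross-validation folds |
| `n_boot` | 10,000 | bootstrap replicates for CIs |

Two parameter choices deserve explanation:

**The penalty form.** "Penalized" LDA admits several formulations; the
ridge form `Sw + λI` is the minimal one that keeps the closed-form
eigen-solution and reduces exactly to Fisher LDA at `λ = 0` (a test checks
this equivalence against a dense generalized-eigenvalue oracle). Scatter
matrices use the MLE divisor `n`, which makes them — and hence the meaning
of a fixed `λ` — invariant under sample duplication. The `"auto"` selection
groups its inner folds by source video: frames of one video are strongly
correlated, and letting them straddle an inner split selects a
near-zero penalty that overfits per-video nuisance (this failure mode was
directly observed during development and is why grouping is not optional).

**The block-normalization regularizer.** Classic HoG implementations add a
vanishing epsilon inside the block norm. On images with genuinely flat
regions that choice amplifies near-zero-energy blocks (background, warp
fill) into unit-norm noise vectors: the nuisance variation they contribute
can exceed the class signal. `norm_eps` is therefore expressed on the scale
of block gradient energy for intensities in [0, 1] (default 0.5, versus
typical stroke-block energies of 2–16): blocks with real structure are
essentially unaffected, empty blocks stay near zero. Setting
`norm_eps = 0` recovers the classic behaviour.

## The synthetic-face generator

There is no public dataset attached to this problem, so the package ships
a parametric generator whose geometry is exactly known. A midline-symmetric
sketch face (face ellipse, brows, eyes, nose, mouth as quadratic curves
through animated corner control points) smiles from neutral to full over
the first 40% of the video and holds; the 68 landmarks are the analytic
curve points, so every downstream stage can be tested against exact
geometry. Unilateral weakness scales the affected mouth corner's smile
excursion by `1 − severity`: at full smile the corner height gap is
exactly `severity × 7 px` (at the 128-px reference scale), which the tests
verify analytically. The patient's left appears on the viewer's right, and
`mirror_video()` applies the standard 68-point left/right index swap, so
right-sided droop is the exact mirror image of left-sided droop.

Severity below 0.05 is labelled normal; severities in [0.05, 0.3) are
refused by default as clinically ambiguous fixtures (overridable).
Severity here is an artifact-defined geometric scale — it is *not*
calibrated to clinical facial-palsy grades. Per-video jitter (head
rotation up to ±8°, scale ±8%, translation ±4 px, a random-direction
illumination gradient of amplitude 0.15, pixel noise sd 0.02 under
`default_jitter()`) emulates hand-held consumer video; frame counts are
drawn uniformly from 12–260 at 30 fps when unspecified, matching the kind
of short smartphone clips the method targets.

What the generator does **not** emulate: skin texture, identity variation,
3-D pose, occlusions (glasses, beards), compression artifacts, or landmark
*detector* error — synthetic landmarks are exact. Passing the synthetic
benchmarks therefore demonstrates that the pipeline recovers the signal it
is designed for under controlled nuisance, not that it reaches any
particular accuracy on real patients.

## Evaluation rules

Ratings on the 1–5 Likert scale collapse to absent (1–2), indeterminate
(3), present (4–5, with a mandatory left/right call); ground truth is the
modal collapsed call across an odd number of raters, laterality the modal
side among present-callers. Ties produce an `unknown` truth that is
flagged and excluded with a warning rather than resolved arbitrarily.

A **false negative** is a truth-present video called absent *or called
present with the wrong laterality*; a **false positive** is calling
weakness on a truth-absent video. This asymmetric rule means converting a
correct detection into a wrong-laterality call lowers sensitivity but can
never change specificity (a property test asserts it). The
laterality-excluded sensitivity analysis (`metrics_no_laterality()`)
rescores wrong-laterality calls as true positives. Indeterminate calls
assert no presence claim and are scored as absent calls.

Confidence intervals are percentile 2.5/97.5 bootstrap over subjects
resampled with replacement, stratified into weakness-present and
weakness-absent subjects with each stratum resampled to its original size
— resampling patients rather than videos respects repeated measures when
a subject contributes both a normal and a weak video. The interval type
(percentile) is a design choice; at the cohort sizes used here its
empirical coverage of a known sensitivity of 0.9 is checked to lie in
90–99%. Rater comparisons bootstrap the difference in a metric with the
same subjects drawn for both raters and report a two-sided p-value from
the position of the difference distribution relative to zero.

Cross-validation folds are stratified by class and grouped by subject
(a subject's class is its weak-side label if it has any weak video):
the same face must never appear in both a training and a test fold.

Fisher's exact test is exposed as a general 2×2 test
(`fisher_exact()`, delegating to `stats::fisher.test`). For comparing
laterality-error rates between raters and an algorithm, two candidate 2×2
constructions exist — errors cross-tabulated as (rater type) ×
(laterality error vs other error), or restricted to detected-present
calls — and the published framing does not pin down which margins were
used; the package exposes the general test and leaves the table
construction to the analyst rather than asserting either reading.

## Numerical choices and degenerate inputs

- Procrustes alignment is closed-form; recovery of a noiseless similarity
  transform is exact to ≤ 1e-7, with no iteration. Zero-variance landmark
  sets raise an error.
- Generalized Procrustes template fitting iterates align-and-average to a
  1e-10 mean-change tolerance, capped at 20 iterations.
- The pLDA eigenproblem is solved through a Cholesky whitening of
  `Sw + λI` (a 1e-12 diagonal jitter guards exact singularity at λ = 0),
  giving a symmetric eigenproblem and deterministic directions; signs are
  fixed by making each direction's largest-magnitude entry positive, and
  the same convention fixes PCA component signs.
- Tie-breaks are fixed and documented everywhere: frame prediction ties
  and vote ties resolve in the class order normal, left, right
  (favouring the non-pathological call); randomized tie-breaking was
  rejected for reproducibility. Inner-CV penalty ties resolve toward the
  smaller penalty.
- Zero metric denominators yield `NA` with a warning, never 0. An AUC over
  a single truth class, and a Fleiss kappa when one category is used
  everywhere (chance agreement 1), raise errors.
- Display rounding is one decimal, half away from zero (`fmt_pct()`).
- All stochastic operations (generator, fold assignment, bootstrap) take
  explicit seeds and are bit-reproducible; RNG state of the caller is
  saved and restored.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` exercise the full chain at desk
scale, chosen to be comfortably separable yet quick: the benchmark cohort
is 30 normal / 15 left / 15 right subjects at severity 0.8 with full
jitter, 12–40 frames per video at 128 px; the mirror-equivariance check
uses a fresh 40-video set (12–24 frames); bootstrap coverage uses 200
simulated rater tables of 93 weak + 96 normal subjects at 1,000 replicates
each. Acceptance thresholds (pooled CV accuracy ≥ 90%, zero laterality
errors among correct detections, ≥ 95% mirror consistency, coverage in
90–99%) are stated in `tests/testthat/test-acceptance.R`.

## Known limitations

- The detector is frame-independent plus voting; it uses no temporal
  dynamics, although asymmetry of *motion* is part of the clinical sign.
- Plurality voting is one reading of "voting classifier"; threshold-based
  variants remain available through the exposed vote fractions.
- The ridge penalty is one member of the penalized-LDA family; other
  penalty structures (e.g. Laplacian smoothing over the HoG grid) would
  need a different solver.
- The synthetic severity scale, while monotone in visible asymmetry, has
  no clinical calibration, and results on synthetic cohorts bound what the
  pipeline can do only under the generator's assumptions listed above.
- Peripheral vs central patterns of weakness (upper-face sparing) are not
  modelled and not classified.
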
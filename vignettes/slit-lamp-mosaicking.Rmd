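---
title: "Mosaicking retinal slit-lamp video: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mosaicking retinal slit-lamp video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the method it implements:
what is modelled, which parameters matter, what the synthetic-data
generator does and does not emulate, and where genuinely open design
choices were settled.

## The problem

A slit lamp illuminates only a narrow vertical band of the retina, to
limit phototoxicity. A video scan therefore consists of frames in which
most pixels carry no retinal information at all; the illuminated band is
non-uniform (luminosity drops toward the slit borders), and specular
glare from the optical path occludes content inside it. Mosaicking such
footage requires knowing *which pixels to trust* (segmentation), *how
frames move relative to one another* (registration), and *how to fuse
overlapping, unevenly lit observations* (blending).

## Segmentation model

Per-pixel gradient boosting (squared loss) on colour and context
features, at 1/4 resolution:

* **Features.** Scenario A: RGB + CIELAB + HSV (9 planes). Scenario B
  adds normalized x and y coordinates (11 planes) — the slit sits near
  the frame centre, so position is highly informative. Scenario C adds a
  12-filter Gabor bank instead (21 planes), on the grounds that genuine
  retinal texture responds more strongly than unlit regions or glare.
* **Boosting.** 200 rounds, shrinkage 0.1, row subsample 0.5, maximal
  depth 3, squared loss; backed by xgboost with one thread and a fixed
  seed, so training is bit-reproducible.
* **Mask chain.** Votes (clipped to [0, 1]) are smoothed with a
  Gaussian of 2 px on the downscaled grid, thresholded at 0.5, then
  upscaled by nearest neighbour. Smoothing happens *before* upscaling;
  single-pixel vote spikes are suppressed while narrow glare borders
  survive. Threshold and smoothing scale are free parameters of
  `predict_mask()`; 0.5/2 px are package defaults, not method constants.
* **Colour conversions** use the standard sRGB→HSV and sRGB→CIELAB
  (D65) definitions; L is rescaled by 1/100 and a, b from [−128, 127] so
  that every plane occupies [0, 1]. Tree splits are scale-invariant, so
  this matters only for interpretability.
* **Gabor defaults.** 4 orientations (0°, 45°, 90°, 135°) × 3
  octave-spaced wavelengths (4, 8, 16 px on the downscaled grid),
  σ = 0.56 λ, aspect 0.5, zero-mean and L1-normalised kernels.

The colour-threshold baseline (`richa_baseline_mask()`) classifies a
pixel as foreground iff `r − 0.7 g > 0`, strictly, at full resolution.
It works on well-lit contact-lens footage but confuses glare (white:
`r − 0.7 g = 0.3 r > 0`) with content, which is precisely what the
learned model fixes.

## Registration

* **Features.** Upright difference-of-Gaussians blobs (4 DoG levels from
  σ₀ = 1.6, low response threshold 0.004, at most 400 points/frame) with
  a 36-dimensional SURF-style gradient-cell descriptor (3 × 3 cells of
  Σdx, Σ|dx|, Σdy, Σ|dy|). Orientation is never estimated: inter-frame
  rotation is assumed negligible, and an upright descriptor is more
  discriminative when that assumption holds. Two details are essential
  in the slit-lamp setting:
  * *Illumination flattening.* The slit profile is static in frame
    coordinates while the retina moves beneath it. Blob detection on raw
    luminance therefore finds "features" anchored to the illumination
    pattern, which match across frames at zero displacement and can
    out-vote the true motion. Dividing luminance by its local mean
    (Gaussian, σ = 4 px — tighter than the border falloff) cancels the
    static pattern while retinal texture at finer scales survives.
  * *Edge suppression and mask erosion.* DoG responds along the slit's
    border edges, where localization along the edge is undefined; a
    principal-curvature ratio test (threshold 10) removes them, and
    keypoints within 4 px of the mask border are dropped.
* **Matching.** Nearest-neighbour descriptor matching with a 0.8 ratio
  test, run in both directions and united; matching is restricted to
  keypoints of the same scale level, since a pure translation preserves
  blob scale.
* **RANSAC.** A translation needs a single correspondence, so each of
  the 100 hypotheses is one match's displacement; inliers lie within a
  3 px Euclidean margin; the winner is refined as the mean displacement
  of its inliers (ties break toward the smaller refined residual), and a
  pair is accepted only with at least 6 correspondences (read as RANSAC
  inliers — only inliers support the transformation).
* **Photometric vetting.** With all-pairs matching, most proposed pairs
  do not overlap at all, and a coincidental 6-inlier consensus arises in
  a small percentage of them — enough to corrupt a least-squares
  solution that trusts every accepted edge equally. Accepted estimates
  are therefore verified photometrically: the two frames' texture planes
  (flattened luminance, band-passed to 1–3 px) are overlaid at the
  estimated translation and must reach a median per-tile normalized
  cross-correlation of 0.5 over the shared foreground (≥ 100 px). The
  tile median (tiles of ≳150 px) ensures one coincidentally aligned
  vessel segment cannot carry the score. Measured on planted
  trajectories, genuine edges score ≥ 0.69 and coincidental ones
  ≤ 0.35, so the 0.5 threshold sits in a wide gap. The 6-inlier rule
  itself is untouched; vetting is a separate pair-level step in
  `register_pairs()` and can be disabled (`ncc_min = 0`).

## Bundle adjustment

Every accepted pair (i, j, Δ) adds one row per axis to a sparse system:
+1 in column i, −1 in column j, right-hand side Δ — the constraint
`x_i − x_j = Δx`. The stacked system `Ax = b` is rank-deficient by
exactly one global-translation degree of freedom per axis; pinning the
anchor frame (first frame of the anchor's connected component) at the
origin removes it, and the anchored system is solved per axis by sparse
normal equations with a Cholesky factorization. Design points:

* x and y are two independent systems sharing A.
* Duplicate edges stay as separate rows; over-determination is the point.
* Components disconnected from the anchor are reported and excluded.
* All constraints are weighted equally by default; weighting by
  √(inlier count) is available (`weight_by_inliers`) but off, since
  equal weighting is the baseline behaviour of the method.
* `chain_positions()` implements the drift-prone alternative —
  integrating consecutive deltas only — and `drift_report()` quantifies
  the difference. On loop trajectories with noisy measurements, least
  squares dominates integration because the loop-closure constraint
  redistributes the accumulated error.

## Blending

The feathering weight of a pixel is its Euclidean distance to the
nearest background pixel of that frame's binary foreground mask
(`EBImage::distmap`): zero outside, increasing toward the interior.
Consequences: dimly lit slit borders contribute little (their distance
is small), and small mis-segmented patches cannot accumulate large
distances, so they are outvoted by genuine content. The mosaic is the
*normalized* weighted mean — the weighted-sum formulation divided by
Σw at each pixel; without the normalization, intensities would scale
with coverage count. Fractional frame positions are placed by bilinear
splatting; integer positions are placed exactly so that tests can assert
bit-level properties. Never-covered canvas is marked by a zero alpha
plane, not black. Blending happens at full resolution with the upscaled
binary masks. `compare_compositors()` implements the three straw-man
compositors (overwrite, unweighted mean, per-pixel median) and scores
seams as the mean luminance-gradient magnitude over mask-border pixels.

## The synthetic-data generator

`scene_spec()` defaults define the study conditions at one quarter of
the clinical sensor scale: 256 × 340 px frames (standing in for
1024 × 1360), a 768² latent fundus, an 80 px slit spanning most of the
frame height, border falloff 10 px, two glare blobs per frame (radius
5–12 px), and Gaussian sensor noise σ = 0.02. Quarter scale keeps a full
40-frame, all-pairs pipeline run around half a minute while preserving
the geometry that matters (slit ≈ ¼ of frame width, ~27 % foreground).
The fundus has a low-frequency orange/red background, nine darker
branching vessel walks radiating from a bright optic-disc analogue, and
fine speckle texture standing in for choroidal mottling. The slit
profile is separable: a boxcar of the slit width convolved with a
Gaussian of the falloff scale horizontally (closed form via Φ), the same
construction with a 4× softer falloff vertically. The ground-truth mask
is illumination ≥ 20 % of slit-centre level and not glare-saturated
(additive glare field > 0.5).

Trajectory presets: `sweep` (monotone horizontal scan), `loop`
(rectangular path returning to its start — the fixture on which
chaining drifts and bundle adjustment does not), `static` (no motion;
the mosaic should reduce to a noise-averaged frame). The default loop
uses 40 frames at 20 px integer steps so that consecutive masks overlap
by far more than the 25 % floor.

What the generator does **not** emulate: lens distortion, rotation and
perspective (excluded by the translation-only model), defocus blur,
vignetting that moves with the eye, saccadic motion blur, and real
choroidal/vessel appearance statistics. Passing tests on this generator
therefore demonstrate the pipeline's correctness and its behaviour under
the modelled degradations (falloff, glare, noise, drift), not clinical
performance; the clinical headline numbers of slit-lamp segmentation
studies require annotated patient footage that is not distributable.

## Evaluation harness

`roc_auc()` sweeps the unique scores (ties grouped) and integrates by
trapezoid, which equals Mann–Whitney concordance; an exhaustive
pairwise-concordance oracle and an independent ROC package cross-check
it in the tests. Cross-validation assigns *frames*, never pixels, to
folds — pixel-level folds would leak a frame's texture into both sides.
The fold curves are averaged vertically (mean TPR on a fixed FPR grid of
step 0.005) and the headline AUC is the area of that mean curve. The
"optimal operating point" is the Youden index (max TPR − FPR) by
default; closest-to-(0, 1) is selectable, as the choice is conventional.
Point metrics report NA (undefined), never 0, on empty denominators.
`fov_gain()` is the percentage increase in covered area,
`trajectory_error()` the per-frame Euclidean error after removing the
unobservable global offset.

## Numerical choices and degenerate inputs

* All RNG flows through per-stage seeds derived from one top-level seed;
  xgboost runs single-threaded so results are bit-reproducible.
* The solver refuses zero-edge systems (except the trivial single-node
  graph, which sits at the origin) and self-edges.
* An all-foreground mask has no background to measure distance to; its
  feathering weights are capped at the image diagonal.
* Frames whose predicted mask covers < 1 % of the image are skipped
  before registration — the 6-correspondence rule would reject them
  anyway, this merely saves the matching work.
* Empty match sets yield a rejected pair with 0 inliers, not an error;
  an empty keypoint set (all-background mask) is likewise legal.

## Known limitations

* Translation-only: real eyes rotate slightly about the optical axis
  and show perspective distortion in the far periphery; both blur the
  mosaic rather than break the pipeline.
* The blob detector and descriptor are implemented in plain R for
  portability; they favour reproducibility over speed, and frame sizes
  beyond ~10⁶ px per frame will be slow.
* At very small frame sizes (≲ 130 px) the texture budget per slit is
  too small for all-pairs matching to be reliable; the package's own
  small test fixtures restrict the pairing window instead.
* Median compositing materializes one plane per frame per channel and
  is intended for modest fixture sizes, not thousand-frame videos.
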
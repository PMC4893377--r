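# slitmosaic

Retinal slit-lamp video mosaicking in R.

The slit lamp is the ophthalmologist's first instrument for examining the
retina, but its video frames are hard to use for documentation: only a
narrow, vertically oriented slit of light illuminates the retina,
luminosity drops off toward the slit borders, and glare from the optical
path occludes content. `slitmosaic` registers and blends such footage
into a single wide-field fundus mosaic in three stages:

1. **Viable-content segmentation.** A gradient-boosted tree classifier
   (200 rounds, shrinkage 0.1, subsample 0.5, depth 3, squared loss)
   scores every pixel of the 4x-downscaled frame from colour (RGB, HSV,
   CIELAB), optional normalized (x, y) position, and an optional
   12-filter Gabor bank (3 scales x 4 orientations). Votes are smoothed,
   thresholded and upscaled into a binary foreground mask. The classic
   colour threshold `r - 0.7 g > 0` is included as a baseline.
2. **Registration and bundle adjustment.** Upright (orientation-free)
   multi-scale blob features, restricted to the foreground, are matched
   between frame pairs; a translation-only model is estimated by RANSAC
   (100 iterations, 3 px margin) and a pair is kept only with at least 6
   correspondences. Every kept pair (i, j, Δ) contributes the constraints
   `x_i − x_j = Δx` and `y_i − y_j = Δy` to a sparse linear system
   `Ax = b` (one row per constraint: +1 at i, −1 at j), which is solved
   by least squares with frame 1 pinned at the origin — the graph-SLAM
   form of bundle adjustment, eliminating the drift that sequential
   chaining accumulates.
3. **Foreground-aware feathering.** Each frame's blending weight is the
   Euclidean distance transform of its foreground mask, so dimly lit
   border pixels and small mis-segmented patches carry little weight; the
   mosaic is the per-pixel weighted mean
   `I_m[p] = Σ_i w_i[p]·t_i(I_i)[p] / Σ_i w_i[p]`.

Because no clinical recordings ship with the package, a synthetic
slit-lamp simulator (`scene_spec()`, `make_fundus()`,
`render_sequence()`) generates textured fundus scenes, slit illumination
with border falloff, glare blobs, sensor noise, ground-truth masks and a
known camera trajectory, making every stage testable end to end.

## Worked example

```r
library(slitmosaic)

spec <- scene_spec(seed = 7)                       # synthetic retina + slit
traj <- make_trajectory("sweep", n_frames = 8, step = 20,
                        origin = c(60, 256))       # 20 px horizontal scan
seq <- render_sequence(spec, traj)
res <- run_pipeline(pipeline_config(source = seq, seed = 7))
str(res$report)
```

```
List of 10
 $ n_frames              : int 8
 $ n_active              : int 8
 $ n_edges               : int 18
 $ n_placed              : int 8
 $ mean_mask_coverage    : num 0.267
 $ max_edge_residual     : num 0.062
 $ rms_edge_residual     : num 0.0424
 $ trajectory_rmse       : num 0.11
 $ endpoint_drift_global : num 0.161
 $ endpoint_drift_chained: num 0.205
```

All 8 frames were segmented (the slit covers ~27 % of each frame),
18 frame pairs passed the 6-correspondence rule, and the bundle-adjusted
positions recover the planted 20 px-per-frame trajectory with an RMSE of
0.11 px; the largest disagreement between any accepted pairwise
measurement and the global solution is 0.06 px. The mosaic canvas
(`res$canvas`) is 258 x 480 px — one frame plus the 7 x 20 px sweep —
and can be written as an RGBA PNG with `write_mosaic()` (alpha marks
never-covered canvas).

For segmentation quality, `crossval()` runs frame-level tenfold
cross-validation and reports the AUC of the vertically averaged ROC
curve; `compare_compositors()` contrasts feathering with overwrite,
mean and median compositing via a seam-gradient metric.

A thin command-line wrapper is installed under
`inst/cli/slitmosaic.R` (`Rscript slitmosaic.R run config.yaml`).

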
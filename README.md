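# cbctmoco — respiratory motion compensation for cone-beam C-arm CT

Rotational C-arm CT acquisitions take several seconds, so respiratory
motion blurs the reconstruction — a serious problem for cardiac
interventions and for pulmonary procedures that need sub-2 mm bronchi to be
visible. `cbctmoco` implements a purely image-based compensation chain for
interventional imaging researchers: the respiration signal is estimated
from the projection images themselves (no gating hardware, perfectly
synchronized by construction) and fed back into the reconstruction.

The chain:

1. **Diaphragm tracking.** One hemidiaphragm contour is tracked through
   the projection sequence as a detector-space parabola
   *v* = *a u*² + *b u* + *c*, fit per frame by RANSAC (20 000 3-point
   samples, 1-px inlier rule) inside a parabolic search band, with
   plausibility constraints on horizontal motion, deformation
   (|Δ*a*/*a*| ≤ 5 %) and motion direction. The vertex is the projected
   diaphragm top.
2. **Motion-corrected triangulation.** Vertices from two views at an
   angular offset (ideally 90°) are rectified onto a common image plane;
   after rectification, static correspondences share the same row, so any
   residual row difference is motion and is removed by replacing the
   partner's row with the reference's. The corrected pair is triangulated
   with the iterative Linear-Eigen method, giving the per-view SI
   displacement *r̂ᵢ* = *z*_ref − *zᵢ* — the respiration signal.
3. **Motion-compensated reconstruction.** Short-scan FDK (cosine
   weighting, Parker weights, Ram-Lak ramp) in which each reference-grid
   voxel is shifted to its position at the view's acquisition time before
   being projected — by the full signal (constant model, rigid coupling)
   or graded linearly in height, *m* = *rᵢ* / (*z*_max − *z*_dia), for
   lung applications.

An analytic dynamic-thorax simulator (ellipsoid phantom, sinusoidal
breathing, closed-form forward projection, ground-truth volumes and
diaphragm positions) makes every stage testable end to end without any
external data. See the methods vignette
(`vignettes/motion-compensation.Rmd`) for the model details and design
rationale.

## Worked example

Desk-scale run (quarter-resolution detector, 50 views over 200°, one 23 mm
breathing cycle):

```r
library(cbctmoco)

det    <- detector_spec(nu = 160, nv = 120, spacing_u = 2.464, spacing_v = 2.464)
geom   <- circular_trajectory(n_views = 50, increment = 4, scan_time = 4,
                              detector = det)
phantom <- phantom_spec()               # 23 mm peak-to-peak, 4 s cycle
stack  <- forward_project(phantom, geom)
stack
#> projection_stack: 50 views of 160 x 120 px, range [0, 7.394]

# seed the tracker at the apex projection in frame 1 and track
apex0 <- project_point(geom$matrices[[1]], diaphragm_top_truth(phantom, 0))
round(apex0, 1)
#>    u    v
#> 79.5 70.8
track <- track_sequence(stack, seed = apex0, rng_seed = 1)
track
#> diaphragm_track: 50 frames, vertex u in [68.7, 116.2], v in [71.7, 86.9] px
#>   accepted: 16, constrained fallback: 34, carried: 0

# triangulate with 90 deg partners and extract the respiration signal
pts <- triangulate_sequence(cbind(track$u_vertex, track$v_vertex), geom,
                            offset_deg = 90)
sig <- smooth_signal(extract_signal(pts, ref_index = 1,
                                    timestamps = geom$timestamps))
sig
#> respiration_signal: 50 views, range [0.552, 22.4] mm (ref view 1)

# reconstruct without and with compensation; compare on the heart crop
vol_unc <- reconstruct(stack, grid = make_grid(64, 3))
vol_cmp <- reconstruct(stack, signal = sig, model_kind = "constant",
                       grid = make_grid(64, 3))
vol_ref <- reconstruct(forward_project(phantom_spec(amplitude_mm = 0), geom),
                       grid = make_grid(64, 3))
ix   <- function(w, k) round((w - vol_ref$origin[k]) / 3) + 1
crop <- list(x = ix(c(-40, 40), 1), y = ix(c(-20, 60), 2),
             z = ix(c(-30, 70), 3))
cat(sprintf("mean heart-crop SSIM: %.2f uncompensated, %.2f compensated\n",
            mean(ssim_slices(vol_ref, vol_unc, crop)),
            mean(ssim_slices(vol_ref, vol_cmp, crop))))
#> mean heart-crop SSIM: 0.65 uncompensated, 0.71 compensated
```

Reading the output: the tracked vertex sweeps 68.7–116.2 px in *u* as the
gantry rotates and the recovered signal spans 0.55–22.4 mm against a true
23 mm amplitude — the slight amplitude loss is the perspective bias of the
contour vertex that the methods vignette discusses. Compensation with the
estimated signal raises the mean structural similarity of the heart region
against the motion-free reference from 0.65 to 0.71 even at this coarse
scale; the frequent `constrained fallback` entries are the motion
constraint acting on the large 4°/frame vertex steps of the 50-view run
(shape is kept, position refit), which is why the track stays locked.

A command-line front end over the same functions ships in
`inst/cli/cbctmoco.R` with subcommands
`simulate | track | triangulate | signal | reconstruct | evaluate |
pipeline`.

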
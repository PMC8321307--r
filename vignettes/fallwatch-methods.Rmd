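---
title: "fallwatch: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fallwatch: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

fallwatch detects falls of a single person from a fixed indoor RGB camera
using only the binary silhouette. This vignette documents the model behind
each stage, the tunable parameters, the synthetic data the tests rely on,
and the design decisions taken where more than one construction was
defensible.

## 1. Silhouette extraction

**Background model.** The empty scene is modelled by the per-pixel,
per-channel *median* of the first `n_train` frames (default 50). A pixel of
a new frame is foreground when its Euclidean RGB distance to the reference
exceeds a per-pixel tolerance, `tolerance_floor + 3·s_p`, where `s_p` is the
Euclidean norm of the per-channel standard deviations observed during
training. The median is robust to brief occlusions during training and the
3-sigma band absorbs sensor noise; on a noise-free scene the tolerance is
exactly the floor (default 20 grey levels), so a uniform 1-level brightness
drift never triggers. This deliberately simple model fills the contract of
heavier codebook-style background subtraction: the pipeline's substance is
in the shadow logic and the later stages, and any foreground/reference pair
can be substituted.

**Shadow test.** Shadows darken the background without changing its
chromaticity. Working in HSV with V min–max normalised per image (a constant
V channel normalises to all zeros by declared rule), a pixel is a shadow
*candidate* when

* `alpha <= F_V / R_V <= beta` (defaults 0.21, 0.99; `R_V = 0` is never
  shadow),
* `|F_S − R_S| <= tau_s` (default 76, 8-bit scale),
* circular `|F_H − R_H| <= tau_h` (default 93, period 256 — hue is an angle
  and 0 and 255 are neighbours; the wrap-around rule is ours, as the 8-bit
  hue encoding leaves it open).

**Gradient refinement.** Texture survives inside a shadow (directions are
preserved, magnitudes scale), while a true object replaces it. Candidates
are grouped into 8-connected blobs; within a blob only pixels whose 3×3
Sobel magnitude reaches `tau_m` (default 6) in *both* frames are
directional, and for those the angle between the two gradient vectors is
`acos` of the normalised dot product, clamped to [−1, 1]. The blob is
confirmed shadow when the fraction of directional pixels with angle below
`tau_a` (default π/10) reaches `tau_c` (default 0.2). Two choices here are
ours: gradients are computed on the *8-bit* V channel (the 0–10 range of
`tau_m` only makes sense there — a normalised-V Sobel cannot exceed ≈ 5.7),
and a blob with *no* directional pixel is confirmed shadow, because the
chromaticity test already flagged it and the refinement exists to rescue
textured foreground, not to rescue flat regions.

**Person selection.** Blobs under `min_blob_area` (50 px) are noise and are
dropped. Survivors are clustered by single-linkage agglomeration under the
bounding-rectangle distance (closest points of the two rectangles, 0 when
they overlap) with merge threshold `merge_distance` (50 px) — single linkage
because a person fragmented by partial occlusion should chain back together.
Each cluster is scored `motion / (1 + d_prev)`: motion is the fraction of
cluster pixels that were background in the previous frame's mask (1 when
there is none) and `d_prev` the centroid distance to the previous person
box. The score operationalises "near the previous position and moving";
ties go to the larger cluster.

## 2. Posture descriptor

The descriptor views the silhouette's bounding box from two reference
points: `P_h = (x_c, 0)` above the box on its centre column, and
`P_v = (width − 1, y_c)` on the right frame border at the box centre row.
(The side point is placed on the *frame border* so the construction works
for non-square frames; if a box touches the frame edge the point is pushed
one pixel past the box — both guards are ours.)

Each fan's extent is defined as the exact angular extent of the box seen
from its reference point: the max-minus-min over the four box corners of the
signed deviation `atan((x − P_hx)/(y − P_hy))` from the vertical through
`P_h` (analogously from `P_v`). For square boxes this collapses to the
familiar `2·atan(halfExtent/d)` with `d` the nearest-point distance; for any
aspect ratio it guarantees every silhouette pixel falls inside the fan. Each
fan is divided into `N` equal sectors and a pixel's sector index is
`floor((angle − angle_min)/Δθ)` clamped to `[0, N−1]` — floor-with-clamp
rather than rounding so the map is total, with boundary ties going to the
higher sector. A degenerate one-pixel-wide box would give a zero extent; the
extent is floored at 1e-6 rad so the division is always defined.

The N×N counts `psi(i, l)` sum to the silhouette pixel count M;
normalisation divides by M, making the histogram invariant to person size
and camera distance up to rasterisation (the residual L1 difference between
a silhouette and its 2× upsampling decays roughly like 10/size — about
0.02 for a 280-px body, which is the size the robustness tests use). The
feature vector appends the global features `theta_v`, `theta_h` and
`theta_h/theta_v` and flattens the histogram row-major (horizontal sector
outer, vertical inner — an arbitrary but fixed order). Note the geometry:
the fan from the *top* point widens with box *width*, the fan from the
*side* point with box *height*, so a lying person has the larger
`theta_h/theta_v`.

`N = 10` is the default: coarser grids merge postures, finer ones leave
sectors empty; 10 is where the four classes separate without the histogram
becoming sparse.

## 3. Posture classification

A C-classification SVM with RBF kernel (one-vs-one multiclass, the standard
libsvm construction) maps feature vectors to `{bend = 1, lie = 2, sit = 3,
stand = 4}`. Defaults `gamma = 0.01`, `cost = 100`. No feature rescaling is
applied: histogram entries already live in [0, 1] and the angle features are
bounded by π, so rescaling would only distort their relative weight.

Evaluation uses the conventional one-vs-rest definitions — precision
`TP/(TP+FP)`, recall `TP/(TP+FN)`, `F = 2PR/(P+R)`, accuracy
`(TP+TN)/total` per class with the overall accuracy micro-averaged
(confusion-matrix trace over total). A metric whose denominator is zero
(e.g. recall of a class absent from the truth) is reported as 0 and flagged
rather than NaN. Cross-validation stratifies folds per class under a fixed
seed and pools the held-out predictions into one confusion matrix; classes
smaller than k fall back to unstratified folds with a warning.

## 4. Fall rules

Four conditions must hold together:

| rule | condition | default |
|---|---|---|
| abnormal | posture ∈ {lie, bend} | — |
| floor | silhouette-pixel floor coverage ≥ threshold | 0.85 |
| transition | frames since last stand/sit frame ≤ max | 25 frames |
| inactivity | rules 1–3 persist with motion ≤ ε | 25 frames, ε = 0.05 |

The floor mask is drawn once on the first frame of a scene. Coverage is
counted over silhouette *pixels* (not the bounding box, which would overrate
sprawled postures). Motion between consecutive masks is `1 − IoU`, zero for
identical masks and for two empty ones. At 25 fps the two 25-frame windows
each mean one second; a deliberate lie-down takes more than 80 frames, which
is what the transition rule separates.

The engine's clock semantics are ours and worth spelling out. The
inactivity clock starts on a frame where abnormal, floor and the
*instantaneous* transition rule hold with motion ≤ ε, and resets whenever
abnormal or floor breaks or motion exceeds ε. The transition count is
*latched* at clock start: the windows are sequential, so the one-second
inactivity wait cannot itself push the transition past its limit. The
`inactive` flag is a *trigger*: it is true exactly when the clock first
reaches the threshold in an armed episode. This makes two desiderata
compatible — "the verdict is fall iff all four flags are true" and "one
episode yields exactly one event". Re-arming requires an observed return to
stand or sit; a person who enters the scene already lying never satisfies
the transition rule (conservative no-fall). Lowering the coverage threshold
or raising the transition limit can only add detections, never remove one.

## 5. Synthetic data: what it does and does not emulate

The generators are pure functions of their seed (byte-identical reruns).

**Postures** (`renderPosture`): stand is a ~3:1 vertical ellipse, lie its
transpose, sit an L-shaped torso-plus-thigh compound, bend a tilted torso
joined to vertical legs. Aspect (±10 %), orientation (±0.08 rad), boundary
shape (smooth low-order angular noise, 2 px) and position (±w/5 — people
appear all over a room, and the global angle features are
position-dependent by design) are jittered per seed; each shape is a single
8-connected component.

**Sequences** (`generateSequence`): a fall rotates the standing figure
about a floor pivot to lying within 15–25 frames and holds it motionless; a
deliberate lie-down does the same over 80–100 frames; sit and bend morph to
their end pose and hold; walk translates the standing figure. The
descending body carries ±1.5 px per-frame sway until it settles — a person
is never perfectly rigid, and this keeps the silhouette's frame-to-frame
motion visible during a slow controlled descent, which is precisely the
property the inactivity rule relies on to tell "still descending" from
"down and motionless". The bend figure straddles the floor edge so its
coverage stays below the 85 % threshold, exercising the floor rule both
ways. Ground truth labels are stand before the transition, bend (or the
morph target) during it, and the end posture after; only fall scripts carry
a truth fall frame (transition end + 25).

**Shadow scenes** (`generateShadowScene`): a sinusoidally textured
background; a shadow ellipse whose RGB values are scaled by ρ ∈ [0.5, 0.9]
(scaling all three channels preserves hue and saturation exactly while
scaling V); a bright, saturated, differently-hued person ellipse with
diagonal texture whose gradients decorrelate from the background. Two
calibration pixels at V = 0 and V = 255 sit in both frames so per-image V
normalisation is identical on both sides and the shadow's normalised
V-ratio equals ρ exactly.

What the fixtures do *not* emulate: real photometric noise, soft shadow
penumbrae, limb articulation, occlusion by furniture, camera distortion, or
the appearance statistics of real posture datasets. Passing tests therefore
demonstrate that the algorithms implement their definitions and that the
discrimination logic works under its stated assumptions — not field
performance on real video.

## 6. Problem sizes and determinism

The test suite cross-validates 4 × 400 jittered silhouettes (the size at
which the classifier bar of 0.95 accuracy / 0.90 per-class recall is
assessed), runs 60 full sequences (20 fall, 20 slow-lying, 20 walk/sit)
through classifier plus rules, checks 20 shadowed scenes against a
brute-force gradient-direction oracle, and compares the histogram against a
naive per-pixel binning oracle on shapes up to 128 × 128 (exact integer
equality) and 280-px bodies for scale robustness. `scripts/acceptance.R`
recomputes the same quantities from a single `--seed`. Every stochastic
step — shape jitter, fold assignment, scene layout — derives from explicit
seeds; identical inputs give bit-identical outputs.

## 7. Known limitations

* One person only; multiple movers confuse the motion/position score.
* The background model is static after training; furniture moves become
  permanent foreground.
* Posture labels come from a classifier trained on synthetic geometry;
  applying the pipeline to real video requires retraining on real
  silhouettes (the CSV/PNG interfaces and the `--masks` bypass exist for
  exactly that).
* A fall ending outside the floor mask (e.g. onto a sofa) is suppressed by
  the floor rule, by design.
* Mask-IoU motion underestimates slow whole-body translation toward the
  camera; the rule thresholds assume the 25 fps, ~2 m mounting geometry
  they were stated for.
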
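# fallwatch

Falls are the leading cause of injury among older adults living alone, and a
single fixed RGB camera can detect them without wearables — and, if only the
binary silhouette is analysed, without storing identifiable images.
**fallwatch** implements a complete silhouette-based fall-detection pipeline
for indoor monitoring:

1. **Silhouette extraction.** A background model (per-pixel median reference
   with a per-pixel tolerance) subtracts the empty scene. Shadows are removed
   in two stages: a chromaticity test marks pixels that darken the reference
   without changing colour, `α ≤ F_V/R_V ≤ β`, `|F_S − R_S| ≤ τ_S`,
   `|F_H − R_H| ≤ τ_H` (V min–max normalised per frame; hue circular with
   period 256), and each candidate blob is then confirmed only if the
   fraction of its textured pixels whose Sobel gradient direction agrees
   between frame and reference, `C_B = (1/N) Σ 𝟙(τ_a − Δθ_p > 0)`, reaches
   the correlation threshold `τ_c`. Small blobs are dropped, the rest are
   clustered by bounding-rectangle distance, and the cluster with the best
   motion/position score becomes the person.
2. **Posture descriptor.** The silhouette's bounding box is seen from a
   reference point above it (P_h) and one beside it (P_v); each fan is split
   into N angular sectors, and the N×N counts of silhouette pixels in sector
   intersections, ψ(i,l), normalised by the pixel count M, form the local
   feature. The fan extents θ_H, θ_V and their ratio θ_H/θ_V are appended,
   giving a feature vector of length N² + 3 (103 for the default N = 10).
3. **Posture classification.** A C-SVM with RBF kernel (γ = 0.01, C = 100,
   one-vs-one) maps each feature vector to one of four postures:
   bend (1), lie (2), sit (3), stand (4).
4. **Fall rules.** A fall is declared when four conditions hold together:
   the posture is abnormal (lie/bend); at least 85 % of the silhouette lies
   on a manually drawn floor mask; at most 25 frames (1 s at 25 fps) passed
   since the last stand/sit frame (deliberate lying takes > 80); and the
   first three conditions persist with negligible silhouette motion
   (1 − IoU ≤ 0.05) for 25 consecutive frames.

Synthetic generators for posture silhouettes, fall / slow-lying / daily
activity sequences and shadowed colour scenes make the whole pipeline
testable without any video data.

## Worked example

```r
library(fallwatch)

## train a posture classifier on synthetic silhouettes (100 per class)
labs  <- rep(names(postureLevels), each = 100)
masks <- lapply(seq_along(labs), function(i) renderPosture(labs[i], seed = i)$mask)
ft    <- featureTable(masks, labels = labs)
model <- trainPostureModel(ft[, 1:103], ft$label)
model
#> PostureModel: SVM-RBF (gamma=0.01, cost=100), 103 features, classes: bend, lie, sit, stand

## simulate a fall, classify every frame, run the rule engine
sq  <- generateSequence("fall", seed = 7)
postures <- sapply(sq$masks, function(m) postureCode(predictPosture(model, featureVector(m))))
dec <- detectFall(buildFrameStates(sq$masks, postures, sq$floor))
fallEvents(dec)
#>   frame transitionFrames coverage
#> 1    79               14        1
```

The event row says: at frame 79 the four rules first held together — the
person reached a lying posture 14 frames (≈ 0.6 s) after last standing,
entirely on the floor, and had then been motionless for 25 frames. That
matches the scripted ground truth (`sq$fallFrame` is 79). Cross-validating
the classifier shows what the descriptor achieves on held-out silhouettes:

```r
kfoldCV(ft[, 1:103], ft$label, k = 10, seed = 1)
#> EvalReport: accuracy 0.9900 over 400 items
```

A thin command-line interface wraps the same functions
(`inst/cli/fallwatch.R` with subcommands `simulate`, `featurize`, `train`,
`detect`, `eval`).

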
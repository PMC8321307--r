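# Projection-histogram descriptor: reference points, fan extents, binning,
# normalization and the combined feature vector.

test_that("reference points follow the box center and frame borders", {
  box <- boundingBox(40, 40, 60, 60)                 # center (50, 50)
  refs <- computeReferencePoints(box, 100, 100)
  expect_equal(unname(refs$ph), c(50, 0))
  expect_equal(unname(refs$pv), c(99, 50))
  refs2 <- computeReferencePoints(boundingBox(50, 40, 70, 60), 200, 100)
  expect_equal(unname(refs2$ph), c(60, 0))
  expect_equal(unname(refs2$pv), c(199, 50))
  # box touching the top edge pushes Ph one pixel outside
  refs3 <- computeReferencePoints(boundingBox(40, 0, 60, 30), 100, 100)
  expect_equal(unname(refs3$ph), c(50, -1))
  # box touching the right border pushes Pv outside
  refs4 <- computeReferencePoints(boundingBox(80, 40, 99, 60), 100, 100)
  expect_equal(unname(refs4$pv[1]), 100)
})

test_that("fan extents equal the corner-angle extents and nearest distances", {
  box <- boundingBox(40, 40, 60, 60)
  refs <- computeReferencePoints(box, 100, 100)
  geo <- computePartitionAngles(box, refs, N = 10)
  expect_equal(geo$dH, 40)
  expect_equal(geo$dV, 39)
  # corner-angle oracle over the four corners
  aH <- aV <- c()
  for (cx in c(40, 60)) for (cy in c(40, 60)) {
    aH <- c(aH, atan((cx - 50) / (cy - 0)))
    aV <- c(aV, atan((cy - 50) / (99 - cx)))
  }
  expect_equal(geo$thetaH, max(aH) - min(aH))
  expect_equal(geo$thetaV, max(aV) - min(aV))
  # for this square box the extents collapse to the 2*atan closed forms
  expect_equal(geo$thetaH, 2 * atan(10 / 40))
  expect_equal(geo$thetaV, 2 * atan(10 / 39))
  expect_equal(geo$deltaH, geo$thetaH / 10)
  expect_error(computePartitionAngles(box, list(ph = c(50, 50), pv = c(99, 50)), 10),
               "outside|above")
})

test_that("histogram counts conserve mass and match the naive oracle", {
  for (seed in 1:10) {
    m <- randomBlobMask(64, 64, seed)
    hist <- projectHistogram(m, N = 10)
    expect_identical(sum(histCounts(hist)), sum(m))
    oracle <- histOracle(m, 10)
    expect_identical(histCounts(hist), oracle$counts)
    expect_equal(hist@thetaH, oracle$thetaH)
    norm <- normalizeHistogram(hist)
    expect_lt(abs(sum(histNormalized(norm)) - 1), 1e-9)
  }
  expect_error(projectHistogram(matrix(FALSE, 8, 8)), "empty silhouette")
})

test_that("mirroring a shape about the box centerline reverses the i index", {
  m <- randomBlobMask(64, 64, 3)
  box <- maskBoundingBox(m)
  # mirror within the box columns (0-based cols x0..x1 <-> x1..x0)
  sub <- m[, (box@x0 + 1):(box@x1 + 1), drop = FALSE]
  m2 <- m
  m2[, (box@x0 + 1):(box@x1 + 1)] <- sub[, rev(seq_len(ncol(sub)))]
  h1 <- histCounts(projectHistogram(m, N = 8))
  h2 <- histCounts(projectHistogram(m2, N = 8))
  expect_identical(sum(h1), sum(h2))
  # i-marginal reverses exactly (boundary ties aside); l-marginal is stable
  # only up to rasterization, since mirroring moves pixels relative to Pv
  expect_lte(sum(abs(rowSums(h2) - rev(rowSums(h1)))) / sum(h1), 0.02)
  expect_lte(sum(abs(colSums(h2) - colSums(h1))) / sum(h1), 0.1)
})

test_that("histogram is exactly invariant under translation with refs following", {
  m <- randomBlobMask(48, 48, 5)
  big <- matrix(FALSE, 80, 96)
  big[10 + seq_len(48), 8 + seq_len(48)] <- m
  shifted <- matrix(FALSE, 80, 96)
  shifted[25 + seq_len(48), 30 + seq_len(48)] <- m
  box1 <- maskBoundingBox(big)
  refs1 <- computeReferencePoints(box1, 96, 80)
  geo1 <- computePartitionAngles(box1, refs1, 10)
  box2 <- maskBoundingBox(shifted)
  refs2 <- list(ph = refs1$ph + c(30 - 8, 25 - 10),
                pv = refs1$pv + c(30 - 8, 25 - 10))
  geo2 <- computePartitionAngles(box2, refs2, 10)
  h1 <- projectHistogram(big, box1, geo1, refs1, 10)
  h2 <- projectHistogram(shifted, box2, geo2, refs2, 10)
  expect_identical(histCounts(h1), histCounts(h2))
})

test_that("normalized histograms are nearly scale invariant", {
  # at camera-near silhouette resolution the residual is rasterization noise,
  # which shrinks roughly like 1/size
  for (seed in c(2, 9)) {
    m <- randomBlobMask(280, 280, seed)
    up <- m[rep(seq_len(280), each = 2), rep(seq_len(280), each = 2)]
    f1 <- matrix(FALSE, 600, 600); f1[41:320, 41:320] <- m
    f2 <- matrix(FALSE, 1200, 1200); f2[81:640, 81:640] <- up
    n1 <- histNormalized(normalizeHistogram(projectHistogram(f1, N = 10)))
    n2 <- histNormalized(normalizeHistogram(projectHistogram(f2, N = 10)))
    expect_lt(sum(abs(n1 - n2)), 0.05)
  }
})

test_that("feature vectors have arity N^2 + 3 and are deterministic", {
  m <- renderPosture("sit", seed = 21)$mask
  expect_length(featureVector(m, N = 5), 28)
  expect_length(featureVector(m, N = 10), 103)
  expect_length(featureVector(m, N = 20), 403)
  expect_identical(featureVector(m), featureVector(m))   # bit-for-bit
  fs <- featureVector(m)
  expect_lt(abs(sum(fs[1:100]) - 1), 1e-9)
  expect_error(featureVector(matrix(FALSE, 10, 10)), "empty")
})

test_that("the global angle ratio separates tall from wide shapes as the oracle computes", {
  tall <- matrix(FALSE, 120, 160); tall[33:112, 68:93] <- TRUE
  wide <- matrix(FALSE, 120, 160); wide[100:112, 41:120] <- TRUE
  fsT <- featureVector(tall); fsW <- featureVector(wide)
  oT <- histOracle(tall, 10); oW <- histOracle(wide, 10)
  expect_equal(unname(fsT["ratio"]), oT$thetaH / oT$thetaV)
  expect_equal(unname(fsW["ratio"]), oW$thetaH / oW$thetaV)
  # the top-point fan grows with box width, the side-point fan with height:
  # the wide lie-like shape has the larger thetaH/thetaV
  expect_gt(fsW["ratio"], fsT["ratio"])
  expect_gt(fsT["theta_v"], fsW["theta_v"])
})
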
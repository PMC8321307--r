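# Background model, subtraction, shadow detection and person selection.

grayFrame <- function(level, h = 20, w = 30) {
  makeFrame(matrix(level, h, w), matrix(level, h, w), matrix(level, h, w))
}

test_that("background model reduces to the constant scene with floor tolerance", {
  frames <- rep(list(grayFrame(80)), 50)
  model <- buildBackgroundModel(frames, nTrain = 50, toleranceFloor = 20)
  expect_equal(as.vector(referenceImage(model)[, , 1]),
               rep(80, 20 * 30))
  expect_true(all(model@tolerance == 20))
  expect_equal(model@nTrain, 50L)
})

test_that("background model matches a per-pixel median oracle under noise", {
  set.seed(42)
  h <- 12; w <- 15
  scene <- array(runif(h * w * 3, 40, 200), dim = c(h, w, 3))
  frames <- lapply(1:50, function(i) {
    fr <- scene + array(sample(-2:2, h * w * 3, TRUE), dim = c(h, w, 3))
    attr(fr, "colorspace") <- "RGB"
    fr
  })
  model <- buildBackgroundModel(frames, nTrain = 50)
  # exact per-pixel median oracle
  stack <- simplify2array(frames)
  med <- apply(stack, 1:3, median)
  expect_equal(unclass(referenceImage(model)), med, ignore_attr = TRUE)
  expect_true(max(abs(referenceImage(model) - scene)) <= 2)
})

test_that("background model rejects short or inconsistent training input", {
  frames <- rep(list(grayFrame(80)), 10)
  expect_error(buildBackgroundModel(frames, nTrain = 50), "insufficient")
  bad <- c(rep(list(grayFrame(80)), 5), list(grayFrame(80, h = 10)),
           rep(list(grayFrame(80)), 44))
  expect_error(buildBackgroundModel(bad, nTrain = 50), "dimension mismatch")
})

test_that("subtraction thresholds color distance per pixel", {
  model <- buildBackgroundModel(rep(list(grayFrame(100)), 50),
                                toleranceFloor = 10)
  expect_false(any(subtractBackground(model, grayFrame(100))))
  expect_false(any(subtractBackground(model, grayFrame(101))))  # below floor
  fr <- grayFrame(100)
  fr[5:12, 10:19, 1] <- 250; fr[5:12, 10:19, 2] <- 30
  mask <- subtractBackground(model, fr)
  # oracle: per-pixel Euclidean distance over all pixels
  oracle <- sqrt((fr[, , 1] - 100)^2 + (fr[, , 2] - 100)^2 +
                 (fr[, , 3] - 100)^2) > 10
  expect_identical(mask, oracle)
  expect_identical(unname(which(mask, arr.ind = TRUE)),
                   unname(which(oracle, arr.ind = TRUE)))
  expect_error(subtractBackground(model, grayFrame(100, h = 5)), "mismatch")
})

test_that("V normalization follows the min-max rule with degenerate guard", {
  v <- matrix(77, 4, 4)
  fr <- hsvTestFrame(matrix(10, 4, 4), matrix(20, 4, 4), v)
  out <- normalizeValueChannel(fr)
  expect_true(all(out[, , 3] == 0))
  v2 <- matrix(c(10, 110, 60, rep(35, 13)), 4, 4)
  out2 <- normalizeValueChannel(hsvTestFrame(matrix(0, 4, 4), matrix(0, 4, 4), v2))
  expect_equal(out2[3, 1, 3], 0.5)            # V=60 between 10 and 110
  expect_equal(min(out2[, , 3]), 0)
  expect_equal(max(out2[, , 3]), 1)
  expect_equal(out2[, , 1], matrix(0, 4, 4))    # H untouched (zeros here)
})

test_that("shadow pixel test honours the ratio, saturation and hue bounds", {
  # frames carry V extremes so normalization is pure scaling
  mkPair <- function(fh, fs, fv, rh, rs, rv) {
    f <- hsvTestFrame(matrix(c(fh, 0, 0), 1, 3), matrix(c(fs, 0, 0), 1, 3),
                      matrix(c(fv, 0, 255), 1, 3))
    r <- hsvTestFrame(matrix(c(rh, 0, 0), 1, 3), matrix(c(rs, 0, 0), 1, 3),
                      matrix(c(rv, 0, 255), 1, 3))
    detectShadowPixels(f, r)[1, 1]
  }
  expect_true(mkPair(15, 40, 120, 10, 30, 200))      # ratio .6, |dS|=10, |dH|=5
  expect_false(mkPair(10, 30, 200, 10, 30, 200))     # ratio 1.0 > beta
  expect_false(mkPair(10, 30, 100, 10, 30, 0))       # R_V = 0 guard
  expect_false(mkPair(15, 120, 120, 10, 30, 200))    # |dS| = 90 > 76
  expect_true(mkPair(250, 40, 120, 10, 30, 200))     # circular |dH| = 16
  expect_false(mkPair(120, 40, 120, 10, 30, 200))    # |dH| = 110 > 93
})

test_that("shadow candidate set grows monotonically in tauS and tauH", {
  for (seed in 1:5) {
    set.seed(seed)
    h <- 16; w <- 16
    f <- hsvTestFrame(matrix(runif(h * w, 0, 255), h, w),
                      matrix(runif(h * w, 0, 255), h, w),
                      matrix(runif(h * w, 0, 255), h, w))
    r <- hsvTestFrame(matrix(runif(h * w, 0, 255), h, w),
                      matrix(runif(h * w, 0, 255), h, w),
                      matrix(runif(h * w, 0, 255), h, w))
    base <- detectShadowPixels(f, r, shadowParams(tauH = 60, tauS = 40))
    wider <- detectShadowPixels(f, r, shadowParams(tauH = 120, tauS = 90))
    expect_true(all(wider[base]))
  }
})

test_that("gradient refinement keeps scaled-V blobs and rescues textured foreground", {
  h <- 24; w <- 24
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), w), h, w)
  vR <- 120 + 60 * sin(2 * pi * x / 6)
  hM <- matrix(40, h, w); sM <- matrix(40, h, w)
  r <- hsvTestFrame(hM, sM, vR)
  blob <- matrix(FALSE, h, w); blob[5:20, 5:20] <- TRUE

  # current = reference with V scaled: directions preserved, delta-theta = 0
  fShadow <- hsvTestFrame(hM, sM, vR * 0.7)
  confirmed <- refineShadowBlobs(blob, fShadow, r)
  expect_true(all(confirmed[blob]))

  # current striped orthogonally to the reference: delta-theta ~ pi/2
  fOrtho <- hsvTestFrame(hM, sM, 120 + 60 * sin(2 * pi * y / 6))
  rejected <- refineShadowBlobs(blob, fOrtho, r)
  expect_false(any(rejected))

  # textureless blob (all gradients below tauM) is shadow by declared rule
  flat <- hsvTestFrame(hM, sM, matrix(120, h, w))
  expect_true(all(refineShadowBlobs(blob, flat, flat)[blob]))
})

test_that("blob confirmation agrees with the brute-force delta-theta oracle", {
  params <- shadowParams()
  for (seed in 1:6) {
    set.seed(seed)
    h <- 32; w <- 32
    vR <- matrix(runif(h * w, 0, 255), h, w)
    vF <- matrix(runif(h * w, 0, 255), h, w)
    hM <- matrix(10, h, w); sM <- matrix(10, h, w)
    cand <- randomBlobMask(h, w, seed + 100)
    out <- refineShadowBlobs(cand, hsvTestFrame(hM, sM, vF),
                             hsvTestFrame(hM, sM, vR), params)
    expect_true(all(cand[out]))          # output subset of candidates
    lab <- fallwatch:::labelComponents(cand)
    for (b in seq_len(max(lab))) {
      px <- which(lab == b, arr.ind = TRUE)
      want <- refineOracleDecision(px, vF, vR, params)
      got <- all(out[px])
      expect_identical(got, want)
      if (!want) expect_false(any(out[px]))
    }
  }
})

test_that("rectangle distance matches closed forms and brute-force search", {
  expect_equal(rectangleDistance(boundingBox(0, 0, 10, 10),
                                 boundingBox(5, 5, 20, 20)), 0)
  expect_equal(rectangleDistance(boundingBox(0, 0, 10, 10),
                                 boundingBox(60, 0, 70, 10)), 50)
  expect_equal(rectangleDistance(boundingBox(0, 0, 10, 10),
                                 boundingBox(40, 50, 50, 60)), 50)  # 30/40/50
  set.seed(7)
  for (k in 1:200) {
    r1 <- c(runif(2, 0, 60), 0, 0); r1[3:4] <- r1[1:2] + runif(2, 1, 30)
    r2 <- c(runif(2, 0, 60), 0, 0); r2[3:4] <- r2[1:2] + runif(2, 1, 30)
    b1 <- boundingBox(r1[1], r1[2], r1[3], r1[4])
    b2 <- boundingBox(r2[1], r2[2], r2[3], r2[4])
    d <- rectangleDistance(b1, b2)
    expect_equal(d, rectangleDistance(b2, b1))        # symmetry
    expect_gte(d, 0)
    expect_lt(abs(d - rectOracle(r1, r2)), 0.5)
    overlap <- r1[1] <= r2[3] && r2[1] <= r1[3] && r1[2] <= r2[4] && r2[2] <= r1[4]
    expect_identical(d == 0, overlap)
  }
})

test_that("person selection filters small blobs and prefers the moving cluster", {
  h <- 100; w <- 160
  fg <- matrix(FALSE, h, w)
  fg[10:15, 10:16] <- TRUE                      # 42 px: below the area floor
  fg[40:89, 40:79] <- TRUE                      # 2000 px person
  res <- extractPersonBlob(fg)
  expect_false(any(res$mask[10:15, 10:16]))
  expect_true(all(res$mask[40:89, 40:79]))
  expect_gte(sum(res$mask), 50)
  expect_true(all(which(res$mask) %in% which(fg)))

  # two clusters: static far blob vs moving blob near the previous position
  fg2 <- matrix(FALSE, h, w)
  fg2[10:29, 10:29] <- TRUE                     # static
  fg2[60:79, 100:119] <- TRUE                   # moving
  prevMask <- matrix(FALSE, h, w)
  prevMask[10:29, 10:29] <- TRUE                # static blob unchanged
  prevMask[60:79, 92:111] <- TRUE               # mover shifted by 8 px
  prev <- list(box = boundingBox(92, 60, 111, 79))
  res2 <- extractPersonBlob(fg2, prevState = prev, prevFrameMask = prevMask)
  expect_true(res2$mask[70, 115])
  expect_false(res2$mask[20, 20])

  expect_error(extractPersonBlob(matrix(FALSE, 5, 5)), "no person")
  small <- matrix(FALSE, 20, 20); small[1:4, 1:4] <- TRUE
  expect_error(extractPersonBlob(small), "no person")
})

test_that("synthetic shadow scenes are cleaned end to end", {
  sc <- generateShadowScene(rho = 0.7, seed = 1)
  model <- buildBackgroundModel(rep(list(sc$reference), 5), nTrain = 5)
  res <- extractSilhouette(model, sc$current)
  expect_gte(mean(!res$mask[sc$shadowMask]), 0.9)
  expect_gte(mean(res$mask[sc$personMask]), 0.9)
})
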
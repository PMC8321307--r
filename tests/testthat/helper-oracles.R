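# Independent oracles and shared fixtures for the test suite.

# Naive per-pixel double-angle binning oracle for the projection histogram:
# recomputes reference points, corner extents and both sector indices for
# every foreground pixel with explicit loops.
histOracle <- function(mask, N) {
  idx <- which(mask, arr.ind = TRUE)
  xs <- idx[, 2] - 1; ys <- idx[, 1] - 1
  x0 <- min(xs); x1 <- max(xs); y0 <- min(ys); y1 <- max(ys)
  xc <- (x0 + x1) / 2; yc <- (y0 + y1) / 2
  phx <- xc; phy <- if (y0 <= 0) y0 - 1 else 0
  pvx <- if (x1 >= ncol(mask) - 1) x1 + 1 else ncol(mask) - 1
  pvy <- yc
  angH <- c(); angV <- c()
  for (cx in c(x0, x1)) for (cy in c(y0, y1)) {
    angH <- c(angH, atan((cx - phx) / (cy - phy)))
    angV <- c(angV, atan((cy - pvy) / (pvx - cx)))
  }
  thetaH <- max(max(angH) - min(angH), 1e-6)
  thetaV <- max(max(angV) - min(angV), 1e-6)
  dH <- thetaH / N; dV <- thetaV / N
  counts <- matrix(0L, N, N)
  for (k in seq_along(xs)) {
    aH <- atan((xs[k] - phx) / (ys[k] - phy))
    aV <- atan((ys[k] - pvy) / (pvx - xs[k]))
    i <- min(max(floor((aH - min(angH)) / dH), 0), N - 1)
    l <- min(max(floor((aV - min(angV)) / dV), 0), N - 1)
    counts[i + 1, l + 1] <- counts[i + 1, l + 1] + 1L
  }
  list(counts = counts, thetaH = thetaH, thetaV = thetaV)
}

# Exact minimum distance between two axis-aligned rectangles via exhaustive
# vertex-to-edge search (plus an interval-overlap test for intersection).
rectOracle <- function(r1, r2) {
  # r = c(x0, y0, x1, y1)
  if (r1[1] <= r2[3] && r2[1] <= r1[3] && r1[2] <= r2[4] && r2[2] <= r1[4])
    return(0)
  corners <- function(r) rbind(c(r[1], r[2]), c(r[3], r[2]),
                               c(r[1], r[4]), c(r[3], r[4]))
  edges <- function(r) list(
    rbind(c(r[1], r[2]), c(r[3], r[2])), rbind(c(r[1], r[4]), c(r[3], r[4])),
    rbind(c(r[1], r[2]), c(r[1], r[4])), rbind(c(r[3], r[2]), c(r[3], r[4])))
  pointSeg <- function(p, a, b) {
    ab <- b - a
    t <- if (sum(ab^2) == 0) 0 else
      max(0, min(1, sum((p - a) * ab) / sum(ab^2)))
    sqrt(sum((a + t * ab - p)^2))
  }
  best <- Inf
  for (p in seq_len(4)) {
    for (e in edges(r2))
      best <- min(best, pointSeg(corners(r1)[p, ], e[1, ], e[2, ]))
    for (e in edges(r1))
      best <- min(best, pointSeg(corners(r2)[p, ], e[1, ], e[2, ]))
  }
  best
}

# 3x3 Sobel at a single pixel (replicated border), computed directly from
# the neighbourhood -- used by the shadow-refinement oracle.
sobelAt <- function(m, r, c) {
  g <- function(dr, dc) m[min(max(r + dr, 1), nrow(m)),
                          min(max(c + dc, 1), ncol(m))]
  gx <- (g(-1, 1) + 2 * g(0, 1) + g(1, 1)) - (g(-1, -1) + 2 * g(0, -1) + g(1, -1))
  gy <- (g(1, -1) + 2 * g(1, 0) + g(1, 1)) - (g(-1, -1) + 2 * g(-1, 0) + g(-1, 1))
  c(gx, gy)
}

# Brute-force blob-level shadow confirmation: per-pixel delta-theta from
# single-pixel Sobel responses on the raw (8-bit) V channels.
refineOracleDecision <- function(blobPixels, vF, vR, params) {
  dts <- c()
  for (k in seq_len(nrow(blobPixels))) {
    r <- blobPixels[k, 1]; c <- blobPixels[k, 2]
    gF <- sobelAt(vF, r, c); gR <- sobelAt(vR, r, c)
    mF <- sqrt(sum(gF^2)); mR <- sqrt(sum(gR^2))
    if (mF < params@tauM || mR < params@tauM) next
    dts <- c(dts, acos(max(-1, min(1, sum(gF * gR) / (mF * mR)))))
  }
  if (!length(dts)) return(TRUE)                    # textureless rule
  mean(params@tauA - dts > 0) >= params@tauC
}

# Random lumpy silhouette: union of a few overlapping ellipses.
randomBlobMask <- function(h, w, seed) {
  set.seed(seed)
  m <- matrix(FALSE, h, w)
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), w), h, w)
  cx0 <- runif(1, w * 0.3, w * 0.7); cy0 <- runif(1, h * 0.3, h * 0.7)
  for (k in 1:3) {
    cx <- cx0 + runif(1, -w * 0.12, w * 0.12)
    cy <- cy0 + runif(1, -h * 0.12, h * 0.12)
    a <- runif(1, w * 0.06, w * 0.2); b <- runif(1, h * 0.06, h * 0.2)
    m <- m | (((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1)
  }
  if (!any(m)) m[round(h / 2), round(w / 2)] <- TRUE
  m
}

# Simple HSV test frames on the 0..255 scale with calibration extremes so
# V normalization is the identity scaling in both frames.
hsvTestFrame <- function(hMat, sMat, vMat) {
  fr <- makeFrame(hMat, sMat, vMat, colorspace = "HSV")
  fr
}

# A crafted rule stream: 5 upright lead frames (or not), then 30 phase
# frames toggling each of the four fall rules independently.
ruleStream <- function(abnormal, onFloor, fastTransition, inactive) {
  lead <- if (fastTransition) rep(4L, 5) else rep(NA_integer_, 5)
  phase <- rep(if (abnormal) 2L else NA_integer_, 30)
  data.frame(
    frame = 1:35,
    posture = c(lead, phase),
    coverage = c(rep(0, 5), rep(if (onFloor) 0.9 else 0.5, 30)),
    motion = c(rep(1, 5), rep(if (inactive) 0 else 0.5, 30)))
}

# Shared trained posture model (cached across test files).
.fixtureEnv <- new.env(parent = emptyenv())
fixtureModel <- function(nPerClass = 100, seedBase = 5000) {
  key <- sprintf("model_%d_%d", nPerClass, seedBase)
  if (is.null(.fixtureEnv[[key]])) {
    labs <- rep(names(postureLevels), each = nPerClass)
    masks <- lapply(seq_along(labs),
                    function(i) renderPosture(labs[i], seed = seedBase + i)$mask)
    ft <- featureTable(masks, labels = labs)
    X <- ft[, setdiff(names(ft), "label")]
    .fixtureEnv[[key]] <- list(model = trainPostureModel(X, ft$label),
                               features = X, labels = ft$label)
  }
  .fixtureEnv[[key]]
}

# Run a generated sequence through classifier + fall rules.
runScenario <- function(scenario, seed, model) {
  sq <- generateSequence(scenario, seed = seed)
  post <- vapply(sq$masks, function(m)
    postureCode(predictPosture(model, featureVector(m))), integer(1))
  dec <- detectFall(buildFrameStates(sq$masks, post, sq$floor))
  list(events = fallEvents(dec), decisions = dec, sequence = sq,
       postures = post)
}
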
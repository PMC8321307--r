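# Silhouette extraction: background modelling and subtraction, shadow
# detection (chromaticity test + blob-level gradient refinement) and
# selection of the person blob.

#' Build a background model from training frames
#'
#' The reference image is the per-pixel, per-channel median of the first
#' \code{nTrain} frames. The per-pixel tolerance is
#' \code{toleranceFloor + 3 * spread}, where spread is the Euclidean norm of
#' the per-channel standard deviations across the training frames, so a
#' noise-free scene gets exactly the floor.
#'
#' @param frames list of RGB frames (h x w x 3 arrays, values 0..255).
#' @param nTrain number of initial frames to train on (default 50).
#' @param toleranceFloor minimum color-distance tolerance (8-bit units).
#' @return A \linkS4class{BackgroundModel}.
#' @export
buildBackgroundModel <- function(frames, nTrain = 50L, toleranceFloor = 20) {
  nTrain <- as.integer(nTrain)
  if (nTrain < 1L) stop("nTrain must be >= 1")
  if (length(frames) < nTrain)
    stop("insufficient training frames: have ", length(frames),
         ", need ", nTrain)
  d <- dim(frames[[1]])
  for (i in seq_len(nTrain))
    if (!identical(dim(frames[[i]]), d))
      stop("dimension mismatch in training frame ", i)
  stack <- array(unlist(frames[seq_len(nTrain)], use.names = FALSE),
                 dim = c(d, nTrain))
  ref <- apply(stack, 1:3, stats::median)
  if (nTrain > 1L) {
    vsum <- apply(stack, 1:3, stats::var)        # per-channel variance
    spread <- sqrt(vsum[, , 1] + vsum[, , 2] + vsum[, , 3])
  } else {
    spread <- matrix(0, d[1], d[2])
  }
  attr(ref, "colorspace") <- "RGB"
  new("BackgroundModel", reference = ref,
      tolerance = toleranceFloor + 3 * spread,
      nTrain = nTrain, floor = toleranceFloor)
}

#' Subtract the background from a frame
#'
#' A pixel is foreground when its Euclidean RGB distance to the reference
#' exceeds the per-pixel tolerance.
#'
#' @param model a \linkS4class{BackgroundModel}.
#' @param frame RGB frame matching the model's dimensions.
#' @return Logical foreground mask.
#' @export
subtractBackground <- function(model, frame) {
  checkSameDims(model@reference, frame, "model reference and frame")
  d2 <- (frame[, , 1] - model@reference[, , 1])^2 +
        (frame[, , 2] - model@reference[, , 2])^2 +
        (frame[, , 3] - model@reference[, , 3])^2
  sqrt(d2) > model@tolerance
}

#' Normalize the V channel of an HSV frame
#'
#' Rescales V to [0, 1] by \code{(V - min V) / (max V - min V)}, improving
#' the contrast between shadow and non-shadow regions. A constant V channel
#' maps to all zeros. H and S are unchanged; the original V range is kept in
#' the \code{vRange} attribute so 8-bit gradients remain computable.
#'
#' @param frame HSV frame.
#' @return HSV frame with V in [0, 1] and attribute \code{vRange}.
#' @export
normalizeValueChannel <- function(frame) {
  if (frameColorspace(frame) != "HSV") stop("frame must be in HSV color space")
  if (!is.null(attr(frame, "vRange"))) return(frame)   # already normalized
  v <- frame[, , 3]
  lo <- min(v); hi <- max(v)
  frame[, , 3] <- if (hi > lo) (v - lo) / (hi - lo) else 0
  attr(frame, "vRange") <- c(lo, hi)
  frame
}

# Accept RGB or HSV input and return HSV with normalized V.
prepareShadowFrame <- function(frame) {
  normalizeValueChannel(rgbToHsvFrame(frame))
}

#' Detect shadow-candidate pixels
#'
#' A pixel is a shadow candidate when the current frame darkens the
#' reference without changing chromaticity:
#' \code{alpha <= F_V / R_V <= beta}, \code{|F_S - R_S| <= tauS} and the
#' circular hue difference (period 256) is at most \code{tauH}. Pixels where
#' \code{R_V == 0} are never shadow. V is the Eq-1 normalized channel; RGB
#' input is converted and normalized automatically.
#'
#' @param current,reference frames of equal dimensions (RGB or HSV).
#' @param params a \linkS4class{ShadowParams}.
#' @return Logical mask of candidate shadow pixels.
#' @export
detectShadowPixels <- function(current, reference, params = shadowParams()) {
  checkSameDims(current, reference, "current and reference frames")
  f <- prepareShadowFrame(current)
  r <- prepareShadowFrame(reference)
  d <- dim(f)
  rv <- r[, , 3]
  ratio <- ifelse(rv > 0, f[, , 3] / rv, NA_real_)
  dh <- abs(f[, , 1] - r[, , 1])
  dh <- pmin(dh, 256 - dh)                       # circular hue difference
  ds <- abs(f[, , 2] - r[, , 2])
  cand <- !is.na(ratio) & ratio >= params@alpha & ratio <= params@beta &
    ds <= params@tauS & dh <= params@tauH
  matrix(cand, d[1], d[2])
}

#' Confirm shadow blobs by gradient-direction correlation
#'
#' Candidate pixels are grouped into 8-connected blobs. Within a blob, only
#' pixels with 8-bit Sobel gradient magnitude >= \code{tauM} in both the
#' current and reference V channel qualify; for each the angle between the
#' two gradient vectors is computed (normalized dot product, argument clamped
#' to [-1, 1]). The blob's correlation C is the fraction of qualifying pixels
#' with angle below \code{tauA}; the blob is confirmed shadow when
#' \code{C >= tauC}. Blobs with no qualifying pixel are textureless and
#' confirmed shadow (the chromaticity test already flagged them; the gradient
#' step exists to rescue textured foreground).
#'
#' @param candidates logical mask from \code{\link{detectShadowPixels}}.
#' @param current,reference the frames the candidates came from.
#' @param params a \linkS4class{ShadowParams}.
#' @return Logical mask of confirmed shadow pixels (a subset of candidates).
#' @export
refineShadowBlobs <- function(candidates, current, reference,
                              params = shadowParams()) {
  checkSameDims(candidates, current, "candidates and current frame")
  checkSameDims(candidates, reference, "candidates and reference frame")
  out <- matrix(FALSE, nrow(candidates), ncol(candidates))
  if (!any(candidates)) return(out)
  f <- prepareShadowFrame(current)
  r <- prepareShadowFrame(reference)
  gf <- sobelGradient(rawValueChannel(f))
  gr <- sobelGradient(rawValueChannel(r))
  lab <- labelComponents(candidates)
  for (b in seq_len(max(lab))) {
    px <- which(lab == b)
    qual <- px[gf$mag[px] >= params@tauM & gr$mag[px] >= params@tauM]
    if (!length(qual)) {            # textureless blob
      out[px] <- TRUE
      next
    }
    dot <- gf$gx[qual] * gr$gx[qual] + gf$gy[qual] * gr$gy[qual]
    den <- gf$mag[qual] * gr$mag[qual]
    dtheta <- acos(pmax(-1, pmin(1, dot / den)))
    cB <- mean(params@tauA - dtheta > 0)
    if (cB >= params@tauC) out[px] <- TRUE
  }
  out
}

#' Minimum distance between two bounding rectangles
#'
#' Euclidean distance between the closest points of the two axis-aligned
#' rectangles; 0 when they overlap or touch.
#'
#' @param b1,b2 \linkS4class{BoundingBox} objects.
#' @return Distance in pixels.
#' @export
rectangleDistance <- function(b1, b2) {
  dx <- max(0, b1@x0 - b2@x1, b2@x0 - b1@x1)
  dy <- max(0, b1@y0 - b2@y1, b2@y0 - b1@y1)
  sqrt(dx^2 + dy^2)
}

#' Isolate the person blob from a foreground mask
#'
#' Blobs smaller than \code{minArea} pixels are removed; survivors are
#' clustered by single-linkage agglomeration under the rectangle-distance
#' merge threshold. Each cluster is scored by \code{motion / (1 + dPrev)},
#' where motion is the fraction of the cluster's pixels not foreground in
#' the previous frame's mask (1 when there is no previous mask) and dPrev is
#' the distance from the cluster centroid to the previous person position
#' (0 when unknown). The top-scoring cluster is the person; ties go to the
#' larger cluster.
#'
#' @param foreground logical foreground mask.
#' @param prevState optional list with element \code{box}, the previous
#'   person \linkS4class{BoundingBox} (element \code{mask} may also be
#'   present).
#' @param prevFrameMask optional logical mask of the previous frame's
#'   foreground.
#' @param minArea minimum blob area in pixels (default 50).
#' @param mergeDistance rectangle-distance merge threshold in pixels
#'   (default 50; blobs strictly closer than this join one cluster).
#' @return list with \code{mask} (logical) and \code{box}
#'   (\linkS4class{BoundingBox}).
#' @export
extractPersonBlob <- function(foreground, prevState = NULL,
                              prevFrameMask = NULL, minArea = 50,
                              mergeDistance = 50) {
  lab <- labelComponents(foreground)
  nb <- max(lab)
  if (nb == 0L) stopInput("no person detected: empty foreground")
  areas <- tabulate(lab[lab > 0L], nbins = nb)
  keep <- which(areas >= minArea)
  if (!length(keep)) stopInput("no person detected: no blob survives area filter")

  boxes <- lapply(keep, function(b) maskBoundingBox(lab == b))
  # single-linkage clustering under the rectangle-distance threshold
  cluster <- seq_along(keep)
  if (length(keep) > 1L) {
    for (i in seq_along(keep)[-1]) for (j in seq_len(i - 1L)) {
      if (rectangleDistance(boxes[[i]], boxes[[j]]) < mergeDistance) {
        old <- cluster[i]
        cluster[cluster == old] <- cluster[j]
      }
    }
  }
  ids <- unique(cluster)
  best <- NULL; bestScore <- -Inf; bestArea <- -1
  for (id in ids) {
    members <- keep[cluster == id]
    cmask <- matrix(lab %in% members, nrow(foreground), ncol(foreground))
    px <- which(cmask)
    motion <- if (is.null(prevFrameMask)) 1 else mean(!prevFrameMask[px])
    dPrev <- 0
    if (!is.null(prevState)) {
      idx <- which(cmask, arr.ind = TRUE)
      centroid <- c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)  # (x, y), 0-based
      pc <- bbCenter(prevState$box)
      dPrev <- sqrt(sum((centroid - pc)^2))
    }
    score <- motion / (1 + dPrev)
    if (score > bestScore + 1e-12 ||
        (abs(score - bestScore) <= 1e-12 && length(px) > bestArea)) {
      best <- cmask; bestScore <- score; bestArea <- length(px)
    }
  }
  list(mask = best, box = maskBoundingBox(best))
}

#' One-shot silhouette extraction for a frame
#'
#' Chains background subtraction, shadow-candidate detection restricted to
#' the foreground, blob-level shadow confirmation, shadow removal and person
#' blob selection.
#'
#' @param model a \linkS4class{BackgroundModel}.
#' @param frame RGB frame.
#' @inheritParams extractPersonBlob
#' @param params a \linkS4class{ShadowParams}.
#' @return list with \code{mask}, \code{box}, and \code{shadow} (the removed
#'   shadow mask).
#' @export
extractSilhouette <- function(model, frame, prevState = NULL,
                              prevFrameMask = NULL, params = shadowParams(),
                              minArea = 50, mergeDistance = 50) {
  fg <- subtractBackground(model, frame)
  shadow <- matrix(FALSE, nrow(fg), ncol(fg))
  if (any(fg)) {
    cand <- detectShadowPixels(frame, model@reference, params) & fg
    if (any(cand))
      shadow <- refineShadowBlobs(cand, frame, model@reference, params)
    fg <- fg & !shadow
  }
  person <- extractPersonBlob(fg, prevState = prevState,
                              prevFrameMask = prevFrameMask,
                              minArea = minArea, mergeDistance = mergeDistance)
  c(person, list(shadow = shadow))
}
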
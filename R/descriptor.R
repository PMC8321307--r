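# Posture descriptor: angular projection histogram over the silhouette
# bounding box, plus the three global angle features.

#' Reference points above and beside a bounding box
#'
#' The top reference point Ph sits on the vertical line through the box
#' center at the image top edge, (xc, 0); the side reference point Pv sits
#' on the horizontal line through the center at the right image border,
#' (frameWidth - 1, yc). If either point would fall inside the box (box
#' touching the image edge) it is pushed to one pixel beyond the box edge.
#'
#' @param box a \linkS4class{BoundingBox}.
#' @param frameWidth,frameHeight frame dimensions in pixels.
#' @return list with \code{ph} and \code{pv}, each a numeric (x, y) pair in
#'   0-based pixel coordinates.
#' @export
computeReferencePoints <- function(box, frameWidth, frameHeight) {
  ctr <- bbCenter(box)
  ph <- c(x = unname(ctr["x"]), y = 0)
  if (box@y0 <= 0) ph["y"] <- box@y0 - 1          # guard: exterior above
  pv <- c(x = frameWidth - 1, y = unname(ctr["y"]))
  if (box@x1 >= frameWidth - 1) pv["x"] <- box@x1 + 1  # guard: exterior right
  list(ph = ph, pv = pv)
}

#' Angular extents and partition steps of the box fans
#'
#' The horizontal fan extent thetaH is the exact angular extent of the
#' bounding box seen from Ph: the max minus min, over the four box corners,
#' of the signed deviation \code{atan((x - ph_x)/(y - ph_y))} from the
#' vertical through Ph. thetaV is the analogous extent from Pv using
#' \code{atan((y - pv_y)/(pv_x - x))}. dH and dV are the Euclidean distances
#' from Ph and Pv to the nearest point of the box. Every silhouette pixel
#' inside the box therefore receives a valid sector for any aspect ratio;
#' for square boxes the extents coincide with 2*atan(halfExtent/d).
#'
#' @param box a \linkS4class{BoundingBox}.
#' @param refs reference points from \code{\link{computeReferencePoints}}.
#' @param N partitions per axis (>= 2).
#' @return list with thetaH, thetaV, deltaH, deltaV, dH, dV and the minimum
#'   corner angles aMinH, aMinV used for binning.
#' @export
computePartitionAngles <- function(box, refs, N = 10L) {
  if (N < 2) stop("N must be >= 2")
  ph <- refs$ph; pv <- refs$pv
  inside <- function(p) p[1] >= box@x0 && p[1] <= box@x1 &&
                        p[2] >= box@y0 && p[2] <= box@y1
  if (inside(ph) || inside(pv)) stop("reference points must lie outside the box")
  if (ph[2] >= box@y0) stop("Ph must lie above the box")
  if (pv[1] <= box@x1) stop("Pv must lie to the right of the box")

  cx <- c(box@x0, box@x1, box@x0, box@x1)
  cy <- c(box@y0, box@y0, box@y1, box@y1)
  aH <- atan((cx - ph[1]) / (cy - ph[2]))
  aV <- atan((cy - pv[2]) / (pv[1] - cx))
  thetaH <- max(max(aH) - min(aH), 1e-6)   # guard for degenerate 1-px extent
  thetaV <- max(max(aV) - min(aV), 1e-6)
  rectDist <- function(p) {
    dx <- max(0, box@x0 - p[1], p[1] - box@x1)
    dy <- max(0, box@y0 - p[2], p[2] - box@y1)
    sqrt(dx^2 + dy^2)
  }
  list(thetaH = thetaH, thetaV = thetaV,
       deltaH = thetaH / N, deltaV = thetaV / N,
       dH = rectDist(ph), dV = rectDist(pv),
       aMinH = min(aH), aMinV = min(aV))
}

#' Project a silhouette onto the N x N sector histogram
#'
#' Each foreground pixel's signed angle from Ph selects the horizontal
#' sector \code{i = floor((a - aMin)/delta)} and its angle from Pv the
#' vertical sector l; both indices are clamped to [0, N-1] (boundary ties go
#' to the higher sector by floor). Every pixel is binned exactly once, so
#' counts sum to the silhouette pixel count M.
#'
#' @param mask logical silhouette mask (non-empty).
#' @param box optional \linkS4class{BoundingBox} (default: tight box of
#'   mask); all foreground pixels must lie inside it.
#' @param geometry optional result of \code{\link{computePartitionAngles}}.
#' @param refs optional result of \code{\link{computeReferencePoints}}.
#' @param N partitions per axis (default 10).
#' @return A \linkS4class{ProjectionHistogram} with counts filled.
#' @export
projectHistogram <- function(mask, box = NULL, geometry = NULL, refs = NULL,
                             N = 10L) {
  N <- as.integer(N)
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty silhouette")
  if (is.null(box)) box <- maskBoundingBox(mask)
  if (is.null(refs))
    refs <- computeReferencePoints(box, ncol(mask), nrow(mask))
  if (is.null(geometry)) geometry <- computePartitionAngles(box, refs, N)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  if (any(x < box@x0 | x > box@x1 | y < box@y0 | y > box@y1))
    stop("foreground pixels outside the bounding box")
  aH <- atan((x - refs$ph[1]) / (y - refs$ph[2]))
  aV <- atan((y - refs$pv[2]) / (refs$pv[1] - x))
  i <- pmin(pmax(floor((aH - geometry$aMinH) / geometry$deltaH), 0), N - 1)
  l <- pmin(pmax(floor((aV - geometry$aMinV) / geometry$deltaV), 0), N - 1)
  counts <- matrix(tabulate(l * N + i + 1, nbins = N * N), N, N)
  new("ProjectionHistogram", counts = counts,
      normalized = matrix(numeric(0), 0, 0), N = N, M = nrow(idx),
      thetaH = geometry$thetaH, thetaV = geometry$thetaV,
      dH = geometry$dH, dV = geometry$dV, box = box, refs = refs)
}

#' Normalize a projection histogram
#'
#' Divides the counts by the silhouette pixel count M so the histogram sums
#' to 1 and becomes invariant to the person's size and camera distance.
#'
#' @param hist a \linkS4class{ProjectionHistogram} with counts.
#' @return The histogram with the \code{normalized} slot filled.
#' @export
normalizeHistogram <- function(hist) {
  if (hist@M == 0L) stop("empty silhouette")
  hist@normalized <- hist@counts / hist@M
  hist
}

#' Combined feature vector of a silhouette
#'
#' The normalized N x N histogram flattened row-major (horizontal sector i
#' outer, vertical sector l inner) followed by the three global features:
#' thetaV, thetaH and the ratio thetaH / thetaV. Length N^2 + 3 (103 for the
#' default N = 10).
#'
#' @param mask logical silhouette mask (non-empty); the frame dimensions are
#'   taken from the mask.
#' @param N partitions per axis (default 10).
#' @return Named numeric vector (\code{f000 ... , theta_v, theta_h, ratio}).
#' @export
featureVector <- function(mask, N = 10L) {
  hist <- normalizeHistogram(projectHistogram(mask, N = N))
  local <- as.vector(t(hist@normalized))     # row-major: i outer, l inner
  fs <- c(local, hist@thetaV, hist@thetaH, hist@thetaH / hist@thetaV)
  w <- max(3L, nchar(as.character(N * N - 1L)))
  names(fs) <- c(sprintf("f%0*d", w, seq_len(N * N) - 1L),
                 "theta_v", "theta_h", "ratio")
  fs
}

#' Feature table for a list of masks
#'
#' @param masks list of logical silhouette masks.
#' @param N partitions per axis.
#' @param labels optional posture labels (codes or names) appended as a
#'   \code{label} column (integer 1..4).
#' @return data.frame, one row per mask.
#' @export
featureTable <- function(masks, N = 10L, labels = NULL) {
  rows <- lapply(masks, featureVector, N = N)
  df <- as.data.frame(do.call(rbind, rows))
  if (!is.null(labels)) {
    if (length(labels) != length(masks))
      stop("labels length must match number of masks")
    df$label <- postureCode(labels)
  }
  df
}
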
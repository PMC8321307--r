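#' @import methods
NULL

#' Posture label space
#'
#' The four posture classes and their integer codes: bend = 1, lie = 2,
#' sit = 3, stand = 4. Lie and bend are the abnormal, fall-related postures.
#'
#' @format Named integer vector of length 4.
#' @export
postureLevels <- c(bend = 1L, lie = 2L, sit = 3L, stand = 4L)

#' Coerce posture codes or names to a factor over the four classes
#'
#' @param x integer codes in 1..4, or character names in
#'   \code{c("bend","lie","sit","stand")}, or an existing factor.
#' @return Factor with levels \code{bend, lie, sit, stand}.
#' @export
postureFactor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    bad <- !x %in% names(postureLevels)
    if (any(bad)) stop("unknown posture name(s): ", paste(unique(x[bad]), collapse = ", "))
    return(factor(x, levels = names(postureLevels)))
  }
  x <- as.integer(x)
  if (any(!x %in% postureLevels, na.rm = TRUE)) stop("posture codes must be in 1..4")
  factor(names(postureLevels)[x], levels = names(postureLevels))
}

#' @describeIn postureFactor integer codes (1..4) from names/factor input.
#' @export
postureCode <- function(x) {
  unname(postureLevels[as.character(postureFactor(x))])
}

# ---- BoundingBox -----------------------------------------------------------

#' Axis-aligned bounding box
#'
#' Pixel coordinates are 0-based with x = column (rightward) and y = row
#' (downward). \code{x0,y0} and \code{x1,y1} are the inclusive min/max pixel
#' coordinates of the box, so a single pixel has \code{x0 == x1}. Width and
#' height are pixel counts (\code{x1 - x0 + 1}).
#'
#' @slot x0,y0,x1,y1 numeric scalar pixel coordinates.
#' @export
setClass("BoundingBox",
  representation(x0 = "numeric", y0 = "numeric", x1 = "numeric", y1 = "numeric"),
  validity = function(object) {
    if (length(object@x0) != 1 || length(object@y0) != 1 ||
        length(object@x1) != 1 || length(object@y1) != 1)
      return("all slots must be scalar")
    if (object@x1 < object@x0 || object@y1 < object@y0)
      return("x1 >= x0 and y1 >= y0 required")
    TRUE
  }
)

#' Construct a BoundingBox
#'
#' @param x0,y0 top-left pixel (0-based).
#' @param x1,y1 bottom-right pixel (inclusive).
#' @return A \linkS4class{BoundingBox}.
#' @export
boundingBox <- function(x0, y0, x1, y1) {
  new("BoundingBox", x0 = as.numeric(x0), y0 = as.numeric(y0),
      x1 = as.numeric(x1), y1 = as.numeric(y1))
}

#' @rdname boundingBox
#' @param box a \linkS4class{BoundingBox}.
#' @export
bbWidth <- function(box) box@x1 - box@x0 + 1

#' @rdname boundingBox
#' @export
bbHeight <- function(box) box@y1 - box@y0 + 1

#' @rdname boundingBox
#' @export
bbCenter <- function(box) c(x = (box@x0 + box@x1) / 2, y = (box@y0 + box@y1) / 2)

setMethod("show", "BoundingBox", function(object) {
  cat(sprintf("BoundingBox [%g,%g]-[%g,%g] (%g x %g px)\n",
              object@x0, object@y0, object@x1, object@y1,
              bbWidth(object), bbHeight(object)))
})

# ---- ShadowParams ----------------------------------------------------------

#' Shadow-detection thresholds
#'
#' Parameters of the chromaticity shadow test and its gradient refinement.
#' A pixel is a shadow candidate when the current frame darkens the reference
#' (normalized V ratio within \code{[alpha, beta]}) without changing
#' chromaticity (circular hue difference within \code{tauH}, saturation
#' difference within \code{tauS}; both on the 8-bit 0..255 scale). Candidate
#' blobs are confirmed when the fraction of textured pixels (8-bit Sobel
#' magnitude \eqn{\ge} \code{tauM} in both frames) whose gradient direction
#' difference is below \code{tauA} reaches the correlation threshold
#' \code{tauC}.
#'
#' @slot alpha,beta V-ratio bounds, \code{0 <= alpha < beta < 1}.
#' @slot tauH,tauS hue/saturation difference thresholds in [0, 255].
#' @slot tauM gradient magnitude threshold (8-bit Sobel units).
#' @slot tauA gradient direction threshold in radians, in [0, pi].
#' @slot tauC correlation threshold in [0, 1].
#' @export
setClass("ShadowParams",
  representation(alpha = "numeric", beta = "numeric", tauH = "numeric",
                 tauS = "numeric", tauM = "numeric", tauA = "numeric",
                 tauC = "numeric"),
  validity = function(object) {
    if (!(object@alpha >= 0 && object@alpha < object@beta && object@beta < 1))
      return("need 0 <= alpha < beta < 1")
    if (object@tauC < 0 || object@tauC > 1) return("tauC must be in [0,1]")
    if (object@tauA < 0 || object@tauA > pi) return("tauA must be in [0,pi]")
    TRUE
  }
)

#' Construct shadow-detection parameters
#'
#' Defaults are the pipeline's operating point: alpha = 0.21, beta = 0.99,
#' tauH = 93, tauS = 76, tauM = 6, tauA = pi/10, tauC = 0.2.
#'
#' @param alpha,beta,tauH,tauS,tauM,tauA,tauC see \linkS4class{ShadowParams}.
#' @return A \linkS4class{ShadowParams} object.
#' @export
shadowParams <- function(alpha = 0.21, beta = 0.99, tauH = 93, tauS = 76,
                         tauM = 6, tauA = pi / 10, tauC = 0.2) {
  new("ShadowParams", alpha = alpha, beta = beta, tauH = tauH, tauS = tauS,
      tauM = tauM, tauA = tauA, tauC = tauC)
}

setMethod("show", "ShadowParams", function(object) {
  cat("ShadowParams:",
      sprintf("alpha=%g beta=%g tauH=%g tauS=%g tauM=%g tauA=%.4g tauC=%g\n",
              object@alpha, object@beta, object@tauH, object@tauS,
              object@tauM, object@tauA, object@tauC))
})

# ---- BackgroundModel -------------------------------------------------------

#' Background model (median reference + per-pixel tolerance)
#'
#' The empty scene is modelled by the per-pixel, per-channel median of the
#' training frames; a pixel of a new frame is foreground when its Euclidean
#' RGB distance to the reference exceeds the per-pixel tolerance
#' (\code{floor + 3 * training spread}).
#'
#' @slot reference numeric array h x w x 3, RGB in [0, 255].
#' @slot tolerance numeric matrix h x w of color-distance thresholds.
#' @slot nTrain integer, number of frames used.
#' @slot floor numeric, the tolerance floor.
#' @export
setClass("BackgroundModel",
  representation(reference = "array", tolerance = "matrix",
                 nTrain = "integer", floor = "numeric"),
  validity = function(object) {
    d <- dim(object@reference)
    if (length(d) != 3 || d[3] != 3) return("reference must be h x w x 3")
    if (!identical(dim(object@tolerance), d[1:2]))
      return("tolerance dimensions must match reference")
    if (object@nTrain < 1L) return("nTrain >= 1 required")
    TRUE
  }
)

setMethod("show", "BackgroundModel", function(object) {
  d <- dim(object@reference)
  cat(sprintf("BackgroundModel: %d x %d scene, %d training frames, tolerance floor %g\n",
              d[2], d[1], object@nTrain, object@floor))
})

#' @rdname buildBackgroundModel
#' @param model a \linkS4class{BackgroundModel}.
#' @export
referenceImage <- function(model) model@reference

# ---- ProjectionHistogram ---------------------------------------------------

#' Angular projection histogram of a silhouette
#'
#' N x N counts of silhouette pixels in the intersections of N angular
#' sectors fanned from a reference point above the bounding box (index i,
#' left to right) and N sectors fanned from a point beside it (index l, top
#' to bottom). \code{normalized} is counts / M once
#' \code{\link{normalizeHistogram}} has been applied (otherwise a 0 x 0
#' matrix).
#'
#' @slot counts integer-valued N x N matrix, \code{sum(counts) == M}.
#' @slot normalized N x N matrix summing to 1, or 0 x 0 before normalization.
#' @slot N integer, partitions per axis.
#' @slot M integer, silhouette pixel count.
#' @slot thetaH,thetaV fan extents (radians) from the top and side points.
#' @slot dH,dV distances (px) from the reference points to the box.
#' @slot box the \linkS4class{BoundingBox} used.
#' @slot refs list with elements \code{ph}, \code{pv} (0-based x,y pairs).
#' @export
setClass("ProjectionHistogram",
  representation(counts = "matrix", normalized = "matrix", N = "integer",
                 M = "integer", thetaH = "numeric", thetaV = "numeric",
                 dH = "numeric", dV = "numeric", box = "BoundingBox",
                 refs = "list"),
  validity = function(object) {
    if (!identical(dim(object@counts), c(object@N, object@N)))
      return("counts must be N x N")
    if (abs(sum(object@counts) - object@M) > 1e-9)
      return("sum(counts) must equal M")
    if (length(object@normalized) &&
        abs(sum(object@normalized) - 1) > 1e-9)
      return("normalized histogram must sum to 1")
    TRUE
  }
)

setMethod("show", "ProjectionHistogram", function(object) {
  cat(sprintf("ProjectionHistogram: N=%d, M=%d pixels, thetaH=%.4f thetaV=%.4f rad%s\n",
              object@N, object@M, object@thetaH, object@thetaV,
              if (length(object@normalized)) " (normalized)" else ""))
})

#' @rdname projectHistogram
#' @param hist a \linkS4class{ProjectionHistogram}.
#' @export
histCounts <- function(hist) hist@counts

#' @rdname projectHistogram
#' @export
histNormalized <- function(hist) {
  if (!length(hist@normalized)) stop("histogram not normalized yet; see normalizeHistogram()")
  hist@normalized
}

# ---- PostureModel ----------------------------------------------------------

#' Trained posture classifier
#'
#' Wraps a C-classification SVM with RBF kernel (one-vs-one multiclass) over
#' feature vectors of length N^2 + 3. No feature rescaling is applied: the
#' histogram entries live in [0, 1] and the angle features are bounded by pi.
#'
#' @slot fit the underlying \code{e1071::svm} fit.
#' @slot gamma,cost RBF kernel width and regularization weight.
#' @slot nFeatures expected feature-vector length.
#' @export
setClass("PostureModel",
  representation(fit = "ANY", gamma = "numeric", cost = "numeric",
                 nFeatures = "integer"),
  validity = function(object) {
    if (object@gamma <= 0 || object@cost <= 0) return("gamma and cost must be > 0")
    TRUE
  }
)

setMethod("show", "PostureModel", function(object) {
  cat(sprintf("PostureModel: SVM-RBF (gamma=%g, cost=%g), %d features, classes: %s\n",
              object@gamma, object@cost, object@nFeatures,
              paste(names(postureLevels), collapse = ", ")))
})

# ---- EvalReport ------------------------------------------------------------

#' Classification evaluation report
#'
#' Confusion matrix (rows = truth, columns = prediction) with micro-averaged
#' accuracy and per-class one-vs-rest precision, recall, F-score and
#' accuracy. Metrics whose denominator is zero are reported as 0 and listed
#' in \code{flags}.
#'
#' @slot confusion square counts matrix, truth in rows.
#' @slot accuracy micro-averaged accuracy (trace / total).
#' @slot perClass data.frame: class, tp, fp, fn, tn, accuracy, precision,
#'   recall, fScore.
#' @slot flags character vector naming zero-denominator metrics.
#' @export
setClass("EvalReport",
  representation(confusion = "matrix", accuracy = "numeric",
                 perClass = "data.frame", flags = "character"),
  validity = function(object) {
    if (nrow(object@confusion) != ncol(object@confusion))
      return("confusion matrix must be square")
    if (object@accuracy < 0 || object@accuracy > 1)
      return("accuracy must be in [0,1]")
    TRUE
  }
)

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: accuracy %.4f over %d items\n",
              object@accuracy, sum(object@confusion)))
  print(object@confusion)
  print(object@perClass[, c("class", "precision", "recall", "fScore")],
        row.names = FALSE)
  if (length(object@flags))
    cat("flagged zero-denominator metrics:", paste(object@flags, collapse = ", "), "\n")
})

# ---- FallRuleParams --------------------------------------------------------

#' Fall decision-rule parameters
#'
#' The four-rule conjunction: (1) posture abnormal (lie or bend); (2)
#' silhouette floor coverage at least \code{coverageThreshold}; (3) at most
#' \code{transitionMax} frames since the last stand/sit frame; (4) the first
#' three rules held with silhouette motion at most \code{motionEpsilon} for
#' at least \code{inactivityMin} consecutive frames. At 25 fps the default
#' 25-frame windows correspond to one second.
#'
#' @slot coverageThreshold fraction in (0, 1], default 0.85.
#' @slot transitionMax frames, default 25.
#' @slot inactivityMin frames, default 25.
#' @slot fps frames per second, default 25.
#' @slot motionEpsilon motion fraction (1 - IoU) treated as "no motion".
#' @export
setClass("FallRuleParams",
  representation(coverageThreshold = "numeric", transitionMax = "numeric",
                 inactivityMin = "numeric", fps = "numeric",
                 motionEpsilon = "numeric"),
  validity = function(object) {
    if (!(object@coverageThreshold > 0 && object@coverageThreshold <= 1))
      return("coverageThreshold must be in (0,1]")
    if (object@transitionMax <= 0) return("transitionMax must be > 0")
    if (object@inactivityMin <= 0) return("inactivityMin must be > 0")
    TRUE
  }
)

#' Construct fall-rule parameters
#'
#' @param coverageThreshold,transitionMax,inactivityMin,fps,motionEpsilon
#'   see \linkS4class{FallRuleParams}.
#' @return A \linkS4class{FallRuleParams} object.
#' @export
fallRuleParams <- function(coverageThreshold = 0.85, transitionMax = 25,
                           inactivityMin = 25, fps = 25,
                           motionEpsilon = 0.05) {
  new("FallRuleParams", coverageThreshold = coverageThreshold,
      transitionMax = transitionMax, inactivityMin = inactivityMin,
      fps = fps, motionEpsilon = motionEpsilon)
}

setMethod("show", "FallRuleParams", function(object) {
  cat(sprintf(
    "FallRuleParams: coverage>=%g, transition<=%g fr, inactivity>=%g fr, fps=%g, motionEps=%g\n",
    object@coverageThreshold, object@transitionMax, object@inactivityMin,
    object@fps, object@motionEpsilon))
})
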
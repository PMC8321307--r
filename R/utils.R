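# Internal helpers: frames, color conversion, connected components, gradients.
#
# Conventions used throughout the package:
#  - masks are logical matrices dim (height, width); mask[y+1, x+1] with
#    0-based pixel coordinates x = column (rightward), y = row (downward);
#  - color frames are numeric arrays dim (height, width, 3) with values in
#    [0, 255] and a "colorspace" attribute ("RGB" or "HSV"). HSV frames hold
#    H and S on the 0..255 scale; V is 0..255 until normalizeValueChannel()
#    rescales it to [0, 1] (recording the original range in attr "vRange").

frameDims <- function(frame) dim(frame)[1:2]

frameColorspace <- function(frame) {
  cs <- attr(frame, "colorspace")
  if (is.null(cs)) "RGB" else cs
}

#' Build a color frame from channel matrices
#'
#' @param c1,c2,c3 numeric matrices (equal dimensions), values in [0, 255].
#' @param colorspace "RGB" or "HSV".
#' @return h x w x 3 numeric array with a \code{colorspace} attribute.
#' @export
makeFrame <- function(c1, c2, c3, colorspace = "RGB") {
  stopifnot(identical(dim(c1), dim(c2)), identical(dim(c1), dim(c3)))
  fr <- array(c(c1, c2, c3), dim = c(dim(c1), 3))
  attr(fr, "colorspace") <- colorspace
  fr
}

checkSameDims <- function(a, b, what = "inputs") {
  da <- if (is.matrix(a)) dim(a) else dim(a)[1:2]
  db <- if (is.matrix(b)) dim(b) else dim(b)[1:2]
  if (!identical(da, db))
    stop("dimension mismatch: ", what, " are ", paste(da, collapse = "x"),
         " vs ", paste(db, collapse = "x"))
  invisible(TRUE)
}

#' Convert an RGB frame to HSV
#'
#' H and S are scaled to 0..255 (hue is circular with period 256); V is
#' max(R,G,B), kept on the 0..255 scale.
#'
#' @param frame RGB frame (values 0..255).
#' @return HSV frame.
#' @export
rgbToHsvFrame <- function(frame) {
  if (frameColorspace(frame) == "HSV") return(frame)
  d <- dim(frame)
  hsv <- grDevices::rgb2hsv(r = as.vector(frame[, , 1]),
                            g = as.vector(frame[, , 2]),
                            b = as.vector(frame[, , 3]),
                            maxColorValue = 255)
  out <- array(0, dim = d)
  out[, , 1] <- hsv[1, ] * 255   # hue, circular period 256
  out[, , 2] <- hsv[2, ] * 255
  out[, , 3] <- hsv[3, ] * 255
  attr(out, "colorspace") <- "HSV"
  out
}

#' @rdname rgbToHsvFrame
#' @export
hsvToRgbFrame <- function(frame) {
  if (frameColorspace(frame) == "RGB") return(frame)
  d <- dim(frame)
  v <- frame[, , 3]
  if (!is.null(attr(frame, "vRange"))) {    # undo normalization
    rg <- attr(frame, "vRange")
    v <- v * (rg[2] - rg[1]) + rg[1]
  }
  cols <- grDevices::hsv(pmin(as.vector(frame[, , 1]) / 255, 1),
                         pmin(as.vector(frame[, , 2]) / 255, 1),
                         pmin(as.vector(v) / 255, 1))
  rgb <- grDevices::col2rgb(cols)
  out <- array(0, dim = d)
  out[, , 1] <- rgb[1, ]; out[, , 2] <- rgb[2, ]; out[, , 3] <- rgb[3, ]
  attr(out, "colorspace") <- "RGB"
  out
}

# Raw (0..255) V channel of an HSV frame, undoing Eq-1 style normalization.
rawValueChannel <- function(frame) {
  v <- frame[, , 3]
  rg <- attr(frame, "vRange")
  if (!is.null(rg)) v <- v * (rg[2] - rg[1]) + rg[1]
  v
}

# 8-connected component labelling (BFS frontier expansion).
# Returns an integer matrix; 0 = background, blobs numbered from 1.
labelComponents <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  todo <- which(mask)
  if (!length(todo)) return(lab)
  nextLab <- 0L
  for (s in todo) {
    if (lab[s] > 0L) next
    nextLab <- nextLab + 1L
    lab[s] <- nextLab
    frontier <- s
    while (length(frontier)) {
      r <- (frontier - 1L) %% h + 1L
      cc <- (frontier - 1L) %/% h + 1L
      cand <- integer(0)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; c2 <- cc + dc
        ok <- rr >= 1L & rr <= h & c2 >= 1L & c2 <= w
        if (any(ok)) cand <- c(cand, (c2[ok] - 1L) * h + rr[ok])
      }
      cand <- unique(cand)
      cand <- cand[mask[cand] & lab[cand] == 0L]
      lab[cand] <- nextLab
      frontier <- cand
    }
  }
  lab
}

# 3x3 Sobel gradient of a matrix, edge rows/cols replicated.
# Returns list(gx, gy, mag).
sobelGradient <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  pad[1, ] <- pad[2, ]; pad[h + 2, ] <- pad[h + 1, ]
  pad[, 1] <- pad[, 2]; pad[, w + 2] <- pad[, w + 1]
  sh <- function(dr, dc) pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# Tight bounding box of a non-empty mask (0-based inclusive pixel coords).
#' Tight bounding box of a silhouette mask
#'
#' @param mask logical matrix.
#' @return A \linkS4class{BoundingBox} (0-based inclusive pixel coordinates).
#' @export
maskBoundingBox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty silhouette")
  boundingBox(min(idx[, 2]) - 1, min(idx[, 1]) - 1,
              max(idx[, 2]) - 1, max(idx[, 1]) - 1)
}

# Run code with a temporary RNG state seeded by `seed`.
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Input-error condition used by the CLI to map to exit code 2.
stopInput <- function(...) {
  stop(structure(class = c("fallwatchInputError", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
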
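# Synthetic fixtures: posture silhouettes, labelled activity sequences with
# floor masks, and shadowed color scenes with ground truth. All generators
# are pure functions of their seed.

# Filled rotated ellipse, optionally with smooth angular boundary noise.
# (cx, cy) 0-based center; semiX/semiY semi-axes before rotation by ang
# (radians, clockwise in pixel coordinates); noise is a function(theta)
# returning a relative boundary perturbation.
rasterEllipse <- function(h, w, cx, cy, semiX, semiY, ang = 0, noise = NULL) {
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), w), h, w)
  dx <- x - cx; dy <- y - cy
  u <- (dx * cos(ang) + dy * sin(ang)) / semiX
  v <- (-dx * sin(ang) + dy * cos(ang)) / semiY
  r2 <- u^2 + v^2
  if (is.null(noise)) return(r2 <= 1)
  lim <- (1 + noise(atan2(v, u)))^2
  r2 <= lim
}

# Smooth angular noise: low-order random Fourier series scaled to `rel`.
makeBoundaryNoise <- function(rel) {
  if (rel <= 0) return(NULL)
  a <- stats::runif(3, -1, 1)
  p <- stats::runif(3, 0, 2 * pi)
  function(theta) {
    g <- a[1] * sin(2 * theta + p[1]) + a[2] * sin(3 * theta + p[2]) +
      a[3] * sin(5 * theta + p[3])
    rel * g / 3
  }
}

largestComponent <- function(mask) {
  lab <- labelComponents(mask)
  if (max(lab) <= 1L) return(mask)
  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  lab == which.max(areas)
}

# Pose geometry shared by renderPosture and generateSequence. `u` morphs
# sit/bend from the standing pose; stand/lie ignore it.
posturePose <- function(label, h, w, cx, cyBase, scale, asp = 1, rot = 0,
                        u = 1, noise = NULL) {
  torsoW <- scale / 6 * asp
  switch(label,
    stand = rasterEllipse(h, w, cx, cyBase - scale / 2, torsoW, scale / 2,
                          ang = rot, noise = noise),
    lie = rasterEllipse(h, w, cx, cyBase - scale / 6, scale / 2, torsoW,
                        ang = rot, noise = noise),
    sit = {
      # torso shortens and a thigh grows out sideways as u goes 0 -> 1
      torsoH <- scale / 2 - u * (scale / 2 - scale / 3.2)
      torso <- rasterEllipse(h, w, cx - u * scale / 8,
                             cyBase - torsoH, scale / 7 * asp, torsoH,
                             ang = rot, noise = noise)
      thigh <- if (u > 0.05)
        rasterEllipse(h, w, cx + u * scale / 6, cyBase - scale / 9,
                      u * scale / 3.2, scale / 7, ang = rot)
      else matrix(FALSE, h, w)
      torso | thigh
    },
    bend = {
      tilt <- u * 1.1 + rot      # torso leans ~63 degrees when u = 1
      legH <- scale / 3.2
      legs <- rasterEllipse(h, w, cx, cyBase - legH, torsoW, legH, ang = rot)
      torso <- rasterEllipse(h, w,
                             cx - sin(tilt) * scale * 0.28,
                             cyBase - legH * 1.6 - cos(tilt) * scale * 0.22,
                             torsoW, scale / 3, ang = tilt, noise = noise)
      legs | torso
    },
    stop("unknown posture label: ", label)
  )
}

#' Render a synthetic posture silhouette
#'
#' Draws one of the four posture classes as a single 8-connected blob:
#' stand is a tall vertical ellipse (about 3:1), lie its horizontal
#' counterpart, sit a compact L-shaped torso-plus-thigh compound and bend a
#' tilted torso joined to vertical legs. Size, aspect, rotation, position
#' and boundary noise are jittered under the seed.
#'
#' @param label posture (code 1..4 or name).
#' @param frameWidth,frameHeight frame dimensions (default 160 x 120).
#' @param scale body height in pixels (>= 20; default 80).
#' @param aspectJitter relative width jitter (default 0.1).
#' @param rotationJitter orientation jitter in radians (default 0.08).
#' @param noiseAmp boundary noise amplitude in pixels (< scale/4; default 2).
#' @param position optional (x, y) of the figure's base point; default is a
#'   jittered frame-dependent standing position.
#' @param seed RNG seed.
#' @return list with \code{mask} (logical matrix) and \code{label} (factor).
#' @export
renderPosture <- function(label, frameWidth = 160L, frameHeight = 120L,
                          scale = 80, aspectJitter = 0.1,
                          rotationJitter = 0.08, noiseAmp = 2,
                          position = NULL, seed = 1L) {
  lab <- as.character(postureFactor(label))
  if (scale < 20) stop("scale must be >= 20 px")
  if (noiseAmp >= scale / 4) stop("noise amplitude must be < scale/4")
  h <- frameHeight; w <- frameWidth
  mask <- withSeed(seed, {
    asp <- 1 + stats::runif(1, -aspectJitter, aspectJitter)
    rot <- stats::runif(1, -rotationJitter, rotationJitter)
    if (is.null(position)) {
      # postures appear anywhere a person might stand in the room
      cx <- w / 2 + stats::runif(1, -w / 5, w / 5)
      cyBase <- h - 8 + stats::runif(1, -10, 4)
    } else {
      cx <- position[1]; cyBase <- position[2]
    }
    noise <- makeBoundaryNoise(noiseAmp / (scale / 6))
    posturePose(lab, h, w, cx, cyBase, scale, asp = asp, rot = rot,
                u = 1, noise = noise)
  })
  if (!any(mask)) stop("shape out of frame")
  list(mask = largestComponent(mask), label = postureFactor(lab))
}

#' Floor mask covering the lower part of the frame
#'
#' @param frameWidth,frameHeight frame dimensions.
#' @param fraction fraction of the frame height that is floor (default 0.6).
#' @return Logical matrix, TRUE on floor rows.
#' @export
defaultFloorMask <- function(frameWidth, frameHeight, fraction = 0.6) {
  y0 <- ceiling(frameHeight * (1 - fraction))
  m <- matrix(FALSE, frameHeight, frameWidth)
  m[(y0 + 1):frameHeight, ] <- TRUE
  m
}

#' Generate a labelled activity sequence
#'
#' Produces per-frame silhouette masks, a floor mask and ground truth for
#' one of five scenarios. \code{fall} rotates a standing figure to lying
#' about a floor pivot within \code{transition} frames (must be <= 25) and
#' holds it motionless; \code{lie_down} does the same slowly (>= 80
#' frames); \code{sit} and \code{bend} morph to their end pose and hold
#' (the bend figure straddles the floor edge, so its floor coverage stays
#' below the fall threshold); \code{walk} translates a standing figure.
#' Ground-truth labels are stand before the transition, bend (fall /
#' lie_down) or the morph midpoint label during it, and the end posture
#' after; the truth verdict is fall only for the \code{fall} scenario.
#'
#' @param scenario one of "fall", "lie_down", "sit", "walk", "bend".
#' @param seed RNG seed.
#' @param frameWidth,frameHeight frame dimensions.
#' @param scale body height in pixels.
#' @param transition transition length in frames (defaults: fall 20,
#'   lie_down 85, sit 20, bend 15; ignored for walk).
#' @param lead number of standing lead-in frames (default 30).
#' @param tail number of motionless tail frames (default 40).
#' @return list: \code{masks} (list of logical matrices), \code{floor},
#'   \code{truth} (data.frame frame/label), \code{scenario},
#'   \code{fallFrame} (expected fall frame, NA when none).
#' @export
generateSequence <- function(scenario = c("fall", "lie_down", "sit", "walk",
                                          "bend"),
                             seed = 1L, frameWidth = 160L, frameHeight = 120L,
                             scale = 80, transition = NULL, lead = 30L,
                             tail = 40L) {
  scenario <- match.arg(scenario)
  lead <- as.integer(lead); tail <- as.integer(tail)
  if (!is.null(transition)) {
    transition <- as.integer(transition)
    if (scenario == "fall" && transition > 25)
      stop("fall scripts require transition <= 25 frames")
    if (scenario == "lie_down" && transition < 80)
      stop("lie_down scripts require transition >= 80 frames")
  }
  h <- frameHeight; w <- frameWidth
  floor <- defaultFloorMask(w, h)

  res <- withSeed(seed, {
    if (is.null(transition))   # per-seed transition duration within the regime
      transition <- switch(scenario,
                           fall = sample(15:25, 1L),
                           lie_down = sample(80:100, 1L),
                           sit = 20L, bend = 15L, walk = 0L)
    asp <- 1 + stats::runif(1, -0.08, 0.08)
    cx <- w / 2 + stats::runif(1, -6, 6)
    cyBase <- h - 8 + stats::runif(1, -3, 0)
    masks <- list(); labels <- character(0)

    standMask <- function(atX = cx, base = cyBase)
      posturePose("stand", h, w, atX, base, scale, asp = asp)

    if (scenario == "walk") {
      n <- lead + tail + 30L
      for (t in seq_len(n)) {
        masks[[t]] <- standMask(atX = cx + 18 * sin(2 * pi * t / n))
        labels[t] <- "stand"
      }
      list(masks = masks, labels = labels, fallFrame = NA_integer_)
    } else if (scenario %in% c("fall", "lie_down")) {
      # rigid rotation of the standing ellipse about a pivot near the feet
      pivotY <- cyBase - scale / 8
      for (t in seq_len(lead)) {
        masks[[t]] <- standMask(); labels[t] <- "stand"
      }
      for (k in seq_len(transition)) {
        uu <- k / transition
        ang <- uu * pi / 2
        # body sway: a descending person is never perfectly rigid, so the
        # silhouette keeps visible frame-to-frame motion until it settles
        jx <- if (uu < 1) stats::runif(1, -1.5, 1.5) else 0
        jy <- if (uu < 1) stats::runif(1, -1, 1) else 0
        cX <- cx + sin(ang) * (scale / 2 - scale / 8) + jx
        cY <- pivotY - cos(ang) * (scale / 2 - scale / 8) + jy
        masks[[lead + k]] <- rasterEllipse(h, w, cX, cY, scale / 6 * asp,
                                           scale / 2, ang = ang)
        labels[lead + k] <- if (uu < 1) "bend" else "lie"
      }
      final <- masks[[lead + transition]]
      for (t in seq_len(tail)) {
        masks[[lead + transition + t]] <- final
        labels[lead + transition + t] <- "lie"
      }
      ff <- if (scenario == "fall") lead + transition + 25L else NA_integer_
      list(masks = masks, labels = labels, fallFrame = ff)
    } else {  # sit or bend
      base <- if (scenario == "bend") h * 0.58 else cyBase
      for (t in seq_len(lead)) {
        masks[[t]] <- standMask(base = base); labels[t] <- "stand"
      }
      for (k in seq_len(transition)) {
        uu <- k / transition
        masks[[lead + k]] <- posturePose(scenario, h, w, cx, base, scale,
                                         asp = asp, u = uu)
        labels[lead + k] <- if (uu < 0.5) "stand" else scenario
      }
      final <- masks[[lead + transition]]
      hold <- max(tail, 60L)
      for (t in seq_len(hold)) {
        masks[[lead + transition + t]] <- final
        labels[lead + transition + t] <- scenario
      }
      list(masks = masks, labels = labels, fallFrame = NA_integer_)
    }
  })
  list(masks = res$masks, floor = floor,
       truth = data.frame(frame = seq_along(res$masks),
                          label = res$labels, stringsAsFactors = FALSE),
       scenario = scenario, fallFrame = res$fallFrame)
}

#' Generate a shadowed scene with ground truth
#'
#' Builds a textured reference frame and a current frame in which an
#' elliptical floor shadow darkens the reference (all three RGB channels
#' scaled by \code{rho}, preserving hue and saturation) and a bright,
#' saturated, differently-hued person occludes it elsewhere with its own
#' texture (gradients decorrelated from the background). Two calibration
#' pixels at V = 0 and V = 255 in the top-left corner keep the V
#' normalization of both frames identical, so the shadow's normalized
#' V-ratio equals \code{rho} exactly.
#'
#' @param rho shadow darkening factor in [0.5, 0.9].
#' @param frameWidth,frameHeight frame dimensions (default 128 x 96).
#' @param seed RNG seed.
#' @return list: \code{reference}, \code{current} (RGB frames),
#'   \code{shadowMask}, \code{personMask} (logical), \code{rho}.
#' @export
generateShadowScene <- function(rho = 0.7, frameWidth = 128L,
                                frameHeight = 96L, seed = 1L) {
  if (rho < 0.5 || rho > 0.9) stop("rho must be in [0.5, 0.9]")
  h <- frameHeight; w <- frameWidth
  withSeed(seed, {
    x <- matrix(rep(0:(w - 1), each = h), h, w)
    y <- matrix(rep(0:(h - 1), w), h, w)
    phx <- stats::runif(1, 0, 2 * pi); phy <- stats::runif(1, 0, 2 * pi)
    vBg <- 0.55 + 0.25 * sin(2 * pi * x / 7 + phx) * cos(2 * pi * y / 9 + phy)
    hueBg <- 110 / 255; satBg <- 0.35
    cols <- grDevices::col2rgb(grDevices::hsv(hueBg, satBg, pmin(pmax(vBg, 0), 1)))
    ref <- array(0, dim = c(h, w, 3))
    ref[, , 1] <- cols[1, ]; ref[, , 2] <- cols[2, ]; ref[, , 3] <- cols[3, ]

    # calibration pixels: fixed V extremes present in both frames
    ref[1, 1, ] <- 0; ref[1, 2, ] <- 255

    shadow <- rasterEllipse(h, w, w * 0.3 + stats::runif(1, -5, 5),
                            h * 0.75, w * 0.2, h * 0.16)
    shadow[1, 1:2] <- FALSE
    person <- rasterEllipse(h, w, w * 0.75 + stats::runif(1, -4, 4),
                            h * 0.45, w * 0.07, h * 0.3)
    person <- person & !shadow
    person[1, 1:2] <- FALSE

    cur <- ref
    for (c in 1:3) {
      ch <- cur[, , c]
      ch[shadow] <- ch[shadow] * rho
      cur[, , c] <- ch
    }
    vP <- 0.72 + 0.2 * sin(2 * pi * (x + y) / 5)
    pcols <- grDevices::col2rgb(grDevices::hsv(0, 0.9, pmin(pmax(vP, 0), 0.95)))
    for (c in 1:3) {
      ch <- cur[, , c]
      ch[person] <- matrix(pcols[c, ], h, w)[person]
      cur[, , c] <- ch
    }
    attr(ref, "colorspace") <- "RGB"
    attr(cur, "colorspace") <- "RGB"
    list(reference = ref, current = cur, shadowMask = shadow,
         personMask = person, rho = rho)
  })
}
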
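# Fall decision engine: four-rule conjunction over a per-frame stream of
# posture, floor coverage and silhouette motion.

#' Fraction of a silhouette lying on the floor
#'
#' @param mask logical silhouette mask (non-empty).
#' @param floor logical floor mask of the same dimensions.
#' @return \code{|mask & floor| / |mask|} in [0, 1].
#' @export
floorCoverage <- function(mask, floor) {
  checkSameDims(mask, floor, "mask and floor")
  m <- sum(mask)
  if (m == 0) stop("empty silhouette")
  sum(mask & floor) / m
}

#' Silhouette motion between consecutive frames
#'
#' One minus the intersection-over-union of the two masks: 0 for identical
#' masks, 1 for disjoint ones. Two empty masks give 0 by convention.
#'
#' @param mask,prev logical masks of equal dimensions.
#' @return Motion fraction in [0, 1].
#' @export
motionScore <- function(mask, prev) {
  checkSameDims(mask, prev, "mask and previous mask")
  u <- sum(mask | prev)
  if (u == 0) return(0)
  1 - sum(mask & prev) / u
}

#' Frames since the last stand or sit posture
#'
#' Counts the frames between \code{current} and the most recent frame (up
#' to and including \code{current}) whose posture is stand or sit. Returns
#' \code{Inf} when no such frame exists (the person was never seen upright),
#' which makes the transition rule fail.
#'
#' @param postures posture labels per frame (codes, names or factor).
#' @param current index (1-based position in \code{postures}) of the frame
#'   to evaluate.
#' @return Non-negative count, or \code{Inf}.
#' @export
transitionFrames <- function(postures, current) {
  codes <- postureCode(postures)
  if (current < 1 || current > length(codes)) stop("current out of range")
  up <- which(codes[seq_len(current)] %in%
              c(postureLevels[["sit"]], postureLevels[["stand"]]))
  if (!length(up)) return(Inf)
  current - max(up)
}

#' Build the per-frame state stream consumed by detectFall
#'
#' @param masks list of silhouette masks, one per frame (NULL entries allowed
#'   for frames with no person; their posture must be NA).
#' @param postures posture labels per frame (NA where no person).
#' @param floor logical floor mask.
#' @return data.frame with frame, posture (integer code), coverage, motion.
#' @export
buildFrameStates <- function(masks, postures, floor) {
  n <- length(masks)
  if (length(postures) != n) stop("length mismatch between masks and postures")
  codes <- suppressWarnings(postureCode(postures))
  coverage <- motion <- numeric(n)
  prev <- NULL
  for (i in seq_len(n)) {
    m <- masks[[i]]
    if (is.null(m) || !any(m)) {
      coverage[i] <- 0; motion[i] <- 1; prev <- NULL
      next
    }
    coverage[i] <- floorCoverage(m, floor)
    motion[i] <- if (is.null(prev)) 1 else motionScore(m, prev)
    prev <- m
  }
  data.frame(frame = seq_len(n), posture = codes,
             coverage = coverage, motion = motion)
}

#' Run the four fall rules over a frame stream
#'
#' Per frame the rules are: \code{abnormal} -- posture is lie or bend;
#' \code{floor} -- floor coverage >= the threshold; \code{transition} -- at
#' most \code{transitionMax} frames since the last stand/sit frame;
#' \code{inactive} -- the first three rules held with motion <=
#' \code{motionEpsilon} for \code{inactivityMin} consecutive frames.
#'
#' The inactivity clock starts on a frame where abnormal, floor and the
#' instantaneous transition rule all hold with no motion, and resets when
#' abnormal or floor breaks or motion exceeds epsilon. The transition rule
#' is latched at clock start, so the inactivity wait itself cannot expire
#' it. \code{inactive} is the trigger flag: it is TRUE exactly when the
#' clock first reaches the threshold in an armed episode, so the verdict is
#' fall if and only if all four flags are TRUE, and a single fall episode
#' yields exactly one event. Re-arming requires a return to stand or sit.
#'
#' @param stream data.frame with columns frame, posture (integer codes,
#'   NA allowed), coverage, motion -- see \code{\link{buildFrameStates}}.
#' @param params a \linkS4class{FallRuleParams}.
#' @return data.frame: frame, posture, coverage, motion, transitionFrames,
#'   ruleAbnormal, ruleFloor, ruleTransition, ruleInactive, verdict
#'   ("fall"/"no_fall").
#' @export
detectFall <- function(stream, params = fallRuleParams()) {
  if (!nrow(stream)) stop("empty stream")
  if (is.unsorted(stream$frame)) stop("stream must be ordered by frame_index")
  n <- nrow(stream)
  abnormal <- c(postureLevels[["lie"]], postureLevels[["bend"]])
  upright <- c(postureLevels[["sit"]], postureLevels[["stand"]])

  lastUp <- -Inf
  clock <- 0L
  latchedTf <- Inf
  armed <- TRUE
  out <- data.frame(frame = stream$frame, posture = stream$posture,
                    coverage = stream$coverage, motion = stream$motion,
                    transitionFrames = NA_real_, ruleAbnormal = FALSE,
                    ruleFloor = FALSE, ruleTransition = FALSE,
                    ruleInactive = FALSE, verdict = "no_fall",
                    stringsAsFactors = FALSE)
  for (t in seq_len(n)) {
    p <- stream$posture[t]
    if (!is.na(p) && p %in% upright) {
      lastUp <- stream$frame[t]
      armed <- TRUE
    }
    tf <- stream$frame[t] - lastUp
    r1 <- !is.na(p) && p %in% abnormal
    r2 <- stream$coverage[t] >= params@coverageThreshold
    r3inst <- tf <= params@transitionMax
    quiet <- stream$motion[t] <= params@motionEpsilon
    if (clock > 0L && r1 && r2 && quiet) {
      clock <- clock + 1L
    } else if (r1 && r2 && r3inst && quiet) {
      clock <- 1L
      latchedTf <- tf
    } else {
      clock <- 0L
      latchedTf <- Inf
    }
    r3 <- if (clock > 0L) latchedTf <= params@transitionMax else r3inst
    r4 <- armed && clock >= params@inactivityMin
    out$transitionFrames[t] <- if (clock > 0L) latchedTf else tf
    out$ruleAbnormal[t] <- r1
    out$ruleFloor[t] <- r2
    out$ruleTransition[t] <- r3
    out$ruleInactive[t] <- r4
    if (r1 && r2 && r3 && r4) {
      out$verdict[t] <- "fall"
      armed <- FALSE
    }
  }
  out
}

#' Extract fall events from a decision trace
#'
#' @param decisions output of \code{\link{detectFall}}.
#' @return data.frame with one row per fall event (frame, transitionFrames,
#'   coverage).
#' @export
fallEvents <- function(decisions) {
  ev <- decisions[decisions$verdict == "fall",
                  c("frame", "transitionFrames", "coverage")]
  rownames(ev) <- NULL
  ev
}
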
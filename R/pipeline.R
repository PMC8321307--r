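# End-to-end pipeline: frames (or pre-extracted masks) -> silhouettes ->
# posture predictions -> fall decisions -> event report.

configShadowParams <- function(cfg) {
  s <- cfg$shadow
  shadowParams(alpha = s$alpha, beta = s$beta, tauH = s$tau_h,
               tauS = s$tau_s, tauM = s$tau_m, tauA = s$tau_a,
               tauC = s$tau_c)
}

configRuleParams <- function(cfg) {
  r <- cfg$rules
  fallRuleParams(coverageThreshold = r$coverage_threshold,
                 transitionMax = r$transition_max,
                 inactivityMin = r$inactivity_min, fps = r$fps,
                 motionEpsilon = r$motion_epsilon)
}

#' Extract silhouettes for a whole frame sequence
#'
#' Trains the background model on the first \code{n_train} frames and runs
#' silhouette extraction (subtraction, shadow removal, person selection)
#' with frame-to-frame tracking on the rest. Frames with no detected person
#' yield NULL masks.
#'
#' @param frames list of RGB frames.
#' @param cfg configuration list (see \code{\link{defaultConfig}}).
#' @return list of masks, aligned with \code{frames} (training frames NULL).
#' @export
extractSequenceMasks <- function(frames, cfg = defaultConfig()) {
  nTrain <- cfg$extraction$n_train
  if (length(frames) <= nTrain)
    stopInput("need more than n_train = ", nTrain, " frames")
  model <- buildBackgroundModel(frames, nTrain = nTrain,
                                toleranceFloor = cfg$extraction$tolerance_floor)
  sp <- configShadowParams(cfg)
  masks <- vector("list", length(frames))
  prevState <- NULL
  prevMask <- NULL
  for (i in (nTrain + 1):length(frames)) {
    res <- tryCatch(
      extractSilhouette(model, frames[[i]], prevState = prevState,
                        prevFrameMask = prevMask, params = sp,
                        minArea = cfg$extraction$min_blob_area,
                        mergeDistance = cfg$extraction$merge_distance),
      fallwatchInputError = function(e) NULL)
    if (!is.null(res)) {
      masks[[i]] <- res$mask
      prevState <- list(box = res$box, mask = res$mask)
      prevMask <- res$mask
    } else {
      prevMask <- NULL
    }
  }
  masks
}

#' Run the full fall-detection pipeline
#'
#' Chains silhouette extraction (or pre-extracted masks), the posture
#' descriptor, the posture classifier and the fall rules, and assembles a
#' per-video event report. Deterministic given inputs and configuration.
#'
#' @param config a configuration list (\code{\link{defaultConfig}} shape) or
#'   the path of a config file. \code{paths$floor} and \code{paths$model}
#'   are required; one of \code{paths$frames} (frame directory) or
#'   \code{paths$masks} (mask directory, bypassing extraction) must be set.
#'   If \code{paths$out} / \code{paths$trace} are set, the JSON report and
#'   the per-frame CSV trace are written there.
#' @return list with \code{report} (video_id, schema, events data.frame) and
#'   \code{trace} (the per-frame decision data.frame).
#' @export
runPipeline <- function(config) {
  cfg <- if (is.character(config)) readConfig(config) else config
  if (!nzchar(cfg$paths$floor)) stopInput("floor mask required")
  if (!nzchar(cfg$paths$model)) stopInput("model file required")
  floor <- readMask(cfg$paths$floor)
  model <- loadPostureModel(cfg$paths$model)

  if (nzchar(cfg$paths$masks)) {
    files <- sort(list.files(cfg$paths$masks, pattern = "\\.png$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stopInput("no masks in ", cfg$paths$masks)
    masks <- lapply(files, readMask)
    masks <- lapply(masks, function(m) if (any(m)) m else NULL)
  } else if (nzchar(cfg$paths$frames)) {
    frames <- readFrames(cfg$paths$frames)
    masks <- extractSequenceMasks(frames, cfg)
  } else {
    stopInput("either a frames or a masks directory is required")
  }
  checkSameDims(floor, if (is.null(masks[[length(masks)]]))
    floor else masks[[length(masks)]], "floor mask and frames")

  n <- cfg$descriptor$n
  postures <- rep(NA_integer_, length(masks))
  for (i in seq_along(masks)) {
    if (is.null(masks[[i]])) next
    fs <- featureVector(masks[[i]], N = n)
    postures[i] <- postureCode(predictPosture(model, fs))
  }
  stream <- buildFrameStates(masks, postures, floor)
  decisions <- detectFall(stream, configRuleParams(cfg))
  events <- fallEvents(decisions)
  report <- list(video_id = cfg$paths$video_id, schema_version = 1L,
                 n_frames = length(masks), events = events)
  if (nzchar(cfg$paths$out)) writeEventReport(report, cfg$paths$out)
  if (nzchar(cfg$paths$trace))
    utils::write.csv(decisions, cfg$paths$trace, row.names = FALSE)
  list(report = report, trace = decisions)
}

#' Write a fall event report as JSON
#'
#' @param report list with video_id, schema_version, n_frames and an events
#'   data.frame.
#' @param path output JSON path.
#' @export
writeEventReport <- function(report, path) {
  payload <- list(
    video_id = report$video_id,
    schema_version = report$schema_version,
    n_frames = report$n_frames,
    events = if (nrow(report$events)) {
      lapply(seq_len(nrow(report$events)), function(i)
        list(frame = report$events$frame[i],
             transition_frames = report$events$transitionFrames[i],
             coverage = report$events$coverage[i]))
    } else list()
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
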
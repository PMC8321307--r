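# Readers and writers: frames, binary masks, feature tables, configuration
# and the serialized posture model. Masks round-trip bit-exactly through
# 8-bit single-channel PNG (foreground = 255).

#' Read an ordered frame sequence from a directory
#'
#' Frames are PNG images read in lexicographic filename order; 8-bit gray
#' images are replicated to three channels, alpha channels are dropped.
#' All frames must share dimensions.
#'
#' @param dirPath directory containing the frames.
#' @return list of RGB frames (h x w x 3, values 0..255).
#' @export
readFrames <- function(dirPath) {
  if (!dir.exists(dirPath)) stopInput("frame directory not found: ", dirPath)
  files <- sort(list.files(dirPath, pattern = "\\.png$", ignore.case = TRUE,
                           full.names = TRUE))
  if (!length(files)) stopInput("no decodable frames in ", dirPath)
  frames <- vector("list", length(files))
  d0 <- NULL
  for (i in seq_along(files)) {
    img <- png::readPNG(files[i]) * 255
    if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
    if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
    attr(img, "colorspace") <- "RGB"
    if (is.null(d0)) d0 <- dim(img)
    else if (!identical(dim(img), d0))
      stopInput("dimension mismatch in frame file ", basename(files[i]))
    frames[[i]] <- img
  }
  frames
}

#' Read and write binary silhouette masks
#'
#' Masks are single-channel PNGs with background 0 and foreground 255; any
#' other pixel value is rejected. write then read is the identity.
#'
#' @param path PNG file path.
#' @return \code{readMask}: logical matrix.
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stopInput("mask file not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  bad <- sum(img != 0 & img != 1)
  if (bad > 0)
    stopInput("mask is not binary: ", bad, " pixel(s) not in {0,255} in ", path)
  img == 1
}

#' @rdname readMask
#' @param mask logical matrix.
#' @export
writeMask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write an RGB frame as PNG
#'
#' @param frame h x w x 3 array, values 0..255.
#' @param path output path.
#' @export
writeFrame <- function(frame, path) {
  png::writePNG(pmin(pmax(frame / 255, 0), 1), path)
  invisible(path)
}

#' Write and read feature tables as CSV
#'
#' Columns f000..f(N^2-1), theta_v, theta_h, ratio and optionally label
#' (integer 1..4). Numeric formatting is fixed at 12 significant digits so
#' output is byte-reproducible.
#'
#' @param df feature data.frame (from \code{\link{featureTable}}).
#' @param path CSV path.
#' @export
writeFeatureTable <- function(df, path) {
  out <- df
  for (cn in names(out))
    if (is.numeric(out[[cn]]) && cn != "label")
      out[[cn]] <- sprintf("%.12g", out[[cn]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stopInput("feature table not found: ", path)
  utils::read.csv(path)
}

#' Persist and restore a trained posture model
#'
#' The file embeds a parameter header (gamma, cost, feature count, schema
#' version) alongside the fit.
#'
#' @param model a \linkS4class{PostureModel}.
#' @param path file path.
#' @export
savePostureModel <- function(model, path) {
  saveRDS(list(header = list(schema = 1L, gamma = model@gamma,
                             cost = model@cost,
                             nFeatures = model@nFeatures),
               fit = model@fit), path)
  invisible(path)
}

#' @rdname savePostureModel
#' @export
loadPostureModel <- function(path) {
  if (!file.exists(path)) stopInput("model file not found: ", path)
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$header))
    stopInput("not a fallwatch model file: ", path)
  new("PostureModel", fit = obj$fit, gamma = obj$header$gamma,
      cost = obj$header$cost, nFeatures = obj$header$nFeatures)
}

# ---- configuration ---------------------------------------------------------

#' Default pipeline configuration
#'
#' Flat section/key structure mirroring the config file format. All values
#' default to the pipeline's operating point.
#'
#' @return Nested named list of sections.
#' @export
defaultConfig <- function() {
  list(
    shadow = list(alpha = 0.21, beta = 0.99, tau_h = 93, tau_s = 76,
                  tau_m = 6, tau_a = pi / 10, tau_c = 0.2),
    extraction = list(n_train = 50, min_blob_area = 50, merge_distance = 50,
                      tolerance_floor = 20),
    descriptor = list(n = 10),
    classifier = list(gamma = 0.01, cost = 100),
    rules = list(coverage_threshold = 0.85, transition_max = 25,
                 inactivity_min = 25, fps = 25, motion_epsilon = 0.05),
    paths = list(frames = "", masks = "", floor = "", model = "", out = "",
                 trace = "", video_id = "video")
  )
}

#' Read and write the pipeline configuration file
#'
#' INI-style text: \code{[section]} headers and \code{key = value} lines;
#' \code{#} starts a comment. Unknown sections or keys are rejected; values
#' round-trip losslessly.
#'
#' @param path config file path.
#' @return \code{readConfig}: nested list merged over
#'   \code{\link{defaultConfig}}.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stopInput("config file not found: ", path)
  cfg <- defaultConfig()
  section <- ""
  for (line in readLines(path, warn = FALSE)) {
    line <- sub("#.*$", "", line)
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[.*\\]$", line)) {
      section <- gsub("^\\[|\\]$", "", line)
      if (!section %in% names(cfg))
        stopInput("unknown config section: [", section, "]")
      next
    }
    kv <- regmatches(line, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3) stopInput("malformed config line: ", line)
    key <- kv[2]; value <- trimws(kv[3])
    if (!nzchar(section)) stopInput("key outside any section: ", key)
    if (!key %in% names(cfg[[section]]))
      stopInput("unknown config key: ", section, ".", key)
    old <- cfg[[section]][[key]]
    cfg[[section]][[key]] <- if (is.numeric(old)) {
      num <- suppressWarnings(as.numeric(value))
      if (is.na(num)) stopInput("non-numeric value for ", section, ".", key)
      num
    } else value
  }
  cfg
}

#' @rdname readConfig
#' @param config nested list as returned by \code{\link{defaultConfig}}.
#' @export
writeConfig <- function(config, path) {
  lines <- character(0)
  for (sec in names(config)) {
    lines <- c(lines, paste0("[", sec, "]"))
    for (key in names(config[[sec]])) {
      v <- config[[sec]][[key]]
      vs <- if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
      lines <- c(lines, paste0(key, " = ", vs))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}
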
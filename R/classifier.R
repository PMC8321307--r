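# Posture classification: C-SVM with RBF kernel (one-vs-one multiclass),
# evaluation metrics and stratified k-fold cross-validation.

asFeatureMatrix <- function(features) {
  m <- as.matrix(features)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("features contain missing values")
  m
}

#' Train the four-class posture classifier
#'
#' Fits a C-classification SVM with radial-basis-function kernel on the
#' combined feature vectors. Defaults gamma = 0.01 and cost = 100. No
#' feature rescaling is applied: histogram entries are already in [0, 1] and
#' the angle features are bounded by pi. Multiclass handling is the usual
#' one-vs-one vote of the underlying libsvm engine; training is
#' deterministic for fixed inputs.
#'
#' @param features numeric matrix or data.frame, one row per silhouette.
#' @param labels posture labels (codes 1..4, names, or factor), one per row.
#' @param gamma RBF kernel width.
#' @param cost regularization weight.
#' @return A \linkS4class{PostureModel}.
#' @export
trainPostureModel <- function(features, labels, gamma = 0.01, cost = 100) {
  x <- asFeatureMatrix(features)
  y <- droplevels(postureFactor(labels))
  if (nrow(x) != length(y))
    stop("length mismatch: ", nrow(x), " feature rows vs ", length(y), " labels")
  if (nlevels(y) < 2) stop("need >=2 classes to train")
  fit <- e1071::svm(x = x, y = y, type = "C-classification",
                    kernel = "radial", gamma = gamma, cost = cost,
                    scale = FALSE)
  new("PostureModel", fit = fit, gamma = gamma, cost = cost,
      nFeatures = ncol(x))
}

#' Predict posture labels
#'
#' @param model a \linkS4class{PostureModel}.
#' @param features a single feature vector or a matrix/data.frame of rows;
#'   length/columns must match the training dimension.
#' @return Factor of posture labels (levels bend, lie, sit, stand).
#' @export
predictPosture <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  x <- asFeatureMatrix(features)
  if (ncol(x) != model@nFeatures)
    stop("dimension mismatch: model expects ", model@nFeatures,
         " features, got ", ncol(x))
  colnames(x) <- colnames(model@fit$SV)
  pred <- stats::predict(model@fit, x)
  postureFactor(as.character(pred))
}

#' One-vs-rest metrics from confusion counts
#'
#' Accuracy (TP+TN)/(TP+FP+TN+FN), precision TP/(TP+FP), recall TP/(TP+FN)
#' and F = 2PR/(P+R). A metric with zero denominator is 0 and flagged.
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @return list with accuracy, precision, recall, fScore, flags (character).
#' @export
binaryMetrics <- function(tp, fp, fn, tn) {
  flags <- character(0)
  total <- tp + fp + fn + tn
  acc <- if (total > 0) (tp + tn) / total else {flags <- c(flags, "accuracy"); 0}
  prec <- if (tp + fp > 0) tp / (tp + fp) else {flags <- c(flags, "precision"); 0}
  rec <- if (tp + fn > 0) tp / (tp + fn) else {flags <- c(flags, "recall"); 0}
  f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else {
    flags <- c(flags, "fScore"); 0
  }
  list(accuracy = acc, precision = prec, recall = rec, fScore = f,
       flags = flags)
}

#' Evaluate posture predictions against truth
#'
#' Builds the 4 x 4 confusion matrix (truth in rows) and computes the
#' micro-averaged accuracy (trace / total) plus per-class one-vs-rest
#' precision, recall, F-score and accuracy.
#'
#' @param predictions,truth posture labels of equal, non-zero length.
#' @return An \linkS4class{EvalReport}.
#' @export
evaluatePostures <- function(predictions, truth) {
  p <- postureFactor(predictions)
  t <- postureFactor(truth)
  if (length(p) != length(t)) stop("length mismatch")
  if (!length(p)) stop("empty input")
  confusion <- table(truth = t, prediction = p)
  confusion <- unclass(confusion)[names(postureLevels), names(postureLevels)]
  total <- sum(confusion)
  rows <- list(); flags <- character(0)
  for (cl in names(postureLevels)) {
    tp <- confusion[cl, cl]
    fp <- sum(confusion[, cl]) - tp
    fn <- sum(confusion[cl, ]) - tp
    tn <- total - tp - fp - fn
    m <- binaryMetrics(tp, fp, fn, tn)
    if (length(m$flags)) flags <- c(flags, paste0(cl, ":", m$flags))
    rows[[cl]] <- data.frame(class = cl, tp = tp, fp = fp, fn = fn, tn = tn,
                             accuracy = m$accuracy, precision = m$precision,
                             recall = m$recall, fScore = m$fScore)
  }
  new("EvalReport", confusion = confusion,
      accuracy = sum(diag(confusion)) / total,
      perClass = do.call(rbind, c(rows, list(make.row.names = FALSE))),
      flags = flags)
}

#' Stratified k-fold cross-validation of the posture classifier
#'
#' Folds are stratified per class under a fixed seed; held-out predictions
#' are pooled into one confusion matrix. If some class has fewer members
#' than k, folds fall back to unstratified assignment with a warning.
#'
#' @param features numeric matrix/data.frame of feature vectors.
#' @param labels posture labels.
#' @param k number of folds (default 10).
#' @param gamma,cost SVM parameters, as in \code{\link{trainPostureModel}}.
#' @param seed RNG seed controlling fold assignment.
#' @return An \linkS4class{EvalReport} over the pooled held-out predictions.
#' @export
kfoldCV <- function(features, labels, k = 10L, gamma = 0.01, cost = 100,
                    seed = 1L) {
  x <- asFeatureMatrix(features)
  y <- postureFactor(labels)
  if (nrow(x) != length(y)) stop("length mismatch")
  if (k < 2) stop("k must be >= 2")
  n <- nrow(x)
  fold <- integer(n)
  withSeed(seed, {
    counts <- table(droplevels(y))
    if (any(counts < k)) {
      warning("some class has fewer than k members; using unstratified folds")
      fold <- sample(rep(seq_len(k), length.out = n))
    } else {
      for (cl in names(counts)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep(seq_len(k), length.out = length(idx))
      }
    }
  })
  pred <- factor(rep(NA_character_, n), levels = names(postureLevels))
  for (f in seq_len(k)) {
    test <- fold == f
    model <- trainPostureModel(x[!test, , drop = FALSE], y[!test],
                               gamma = gamma, cost = cost)
    pred[test] <- predictPosture(model, x[test, , drop = FALSE])
  }
  evaluatePostures(pred, y)
}
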
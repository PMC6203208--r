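#' Confusion counts for one class
#'
#' Counts true/false positives/negatives of a prediction with respect to
#' one class treated as positive.
#'
#' @param truth,pred character vectors of class labels.
#' @param positive the class counted as positive.
#' @return list with integer components `tp`, `fp`, `tn`, `fn`.
#' @export
confusionCounts <- function(truth, pred, positive) {
  stopifnot(length(truth) == length(pred))
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  tn <- sum(truth != positive & pred != positive)
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Precision, recall and F-measure
#'
#' \eqn{P = TP / (TP + FP)}, \eqn{R = TP / (TP + FN)},
#' \eqn{F = 2 P R / (P + R)}. Degenerate denominators yield 0.
#'
#' @param c list of confusion counts as from [confusionCounts()].
#' @return numeric(1) in \[0, 1\].
#' @examples
#' fMeasure(list(tp = 9, fp = 1, tn = 0, fn = 3)) # 2*0.9*0.75/1.65
#' @export
precisionScore <- function(c) {
  d <- c$tp + c$fp
  if (d == 0) 0 else c$tp / d
}

#' @rdname precisionScore
#' @export
recallScore <- function(c) {
  d <- c$tp + c$fn
  if (d == 0) 0 else c$tp / d
}

#' @rdname precisionScore
#' @export
fMeasure <- function(c) {
  p <- precisionScore(c)
  r <- recallScore(c)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' Macro- and weighted-average F-measure of a prediction
#'
#' `macroFMeasure` averages the per-class F-measures with equal weight;
#' `weightedFMeasure` weights them by class frequency in `truth` (the
#' convention of some toolkits' summary output). Classes are those
#' occurring in `truth`.
#'
#' @param truth,pred character vectors of class labels.
#' @return numeric(1).
#' @export
macroFMeasure <- function(truth, pred) {
  classes <- sort(unique(as.character(truth)))
  mean(vapply(classes, function(cl) fMeasure(confusionCounts(truth, pred, cl)),
              numeric(1L)))
}

#' @rdname macroFMeasure
#' @export
weightedFMeasure <- function(truth, pred) {
  truth <- as.character(truth)
  classes <- sort(unique(truth))
  w <- vapply(classes, function(cl) mean(truth == cl), numeric(1L))
  f <- vapply(classes, function(cl) fMeasure(confusionCounts(truth, pred, cl)),
              numeric(1L))
  sum(w * f)
}

#' Stratified k-fold cross-validation of a learner
#'
#' Samples are assigned to `k` folds stratified by class (seeded); for
#' each fold the learner is fit on the remaining samples and evaluated on
#' the held-out fold. Per-class F-measures, their macro average and the
#' frequency-weighted average are reported per fold, along with the means
#' over folds.
#'
#' @param m a [GeneMatrix-class], or a numeric samples x features matrix
#'   (then `labels` must be given).
#' @param learner an `"omicsLearner"` (see [ripperLearner()]) or any list
#'   with a `fit(x, y)` component returning a model with a `predict`
#'   method.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param labels class labels when `m` is a plain matrix.
#' @return list with components `folds` (data.frame with one row per
#'   fold: per-class F, `macroF`, `weightedF`), `meanMacroF`,
#'   `meanWeightedF`, and `foldAssignment`.
#' @export
crossValidate <- function(m, learner = ripperLearner(), k = 10L, seed = 1L,
                          labels = NULL) {
  if (is(m, "GeneMatrix")) {
    labels <- unname(classLabels(m))
    x <- matrixValues(m)
  } else {
    x <- as.matrix(m)
  }
  stopifnot(!is.null(labels), length(labels) == nrow(x), k >= 2L)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  tooSmall <- classes[table(labels)[classes] < k]
  if (length(tooSmall)) {
    stop("class(es) ", paste(tooSmall, collapse = ", "), " have fewer than ",
         k, " members; use a smaller k", call. = FALSE)
  }
  folds <- stratifiedFolds(labels, k, seed)
  rows <- lapply(seq_len(k), function(f) {
    test <- folds == f
    model <- learner$fit(x[!test, , drop = FALSE], labels[!test])
    pred <- predict(model, x[test, , drop = FALSE])
    truth <- labels[test]
    perClass <- vapply(classes, function(cl) {
      fMeasure(confusionCounts(truth, pred, cl))
    }, numeric(1L))
    c(perClass, macroF = macroFMeasure(truth, pred),
      weightedF = weightedFMeasure(truth, pred))
  })
  folds_df <- as.data.frame(do.call(rbind, rows))
  folds_df <- cbind(fold = seq_len(k), folds_df)
  list(folds = folds_df,
       meanMacroF = mean(folds_df$macroF),
       meanWeightedF = mean(folds_df$weightedF),
       foldAssignment = folds)
}

#' Exhaustive grid search for learner parameters by cross-validation
#'
#' Evaluates every parameter set of the grid with [crossValidate()] and
#' returns the one maximizing mean macro F-measure (ties resolved to the
#' first in grid order).
#'
#' @param m a [GeneMatrix-class] or numeric matrix (with `labels`).
#' @param learnerFactory function taking one parameter list and returning
#'   a learner, e.g. `function(p) do.call(ripperLearner, p)`.
#' @param grid non-empty list of parameter lists.
#' @param k,seed,labels as in [crossValidate()].
#' @return list with `best` (the winning parameter list), `bestIndex`,
#'   and `scores` (mean macro-F per grid entry).
#' @export
tuneParameters <- function(m, learnerFactory, grid, k = 10L, seed = 1L,
                           labels = NULL) {
  if (!length(grid)) stop("parameter grid must be non-empty", call. = FALSE)
  scores <- vapply(grid, function(p) {
    crossValidate(m, learnerFactory(p), k = k, seed = seed,
                  labels = labels)$meanMacroF
  }, numeric(1L))
  bestIndex <- which.max(scores)
  list(best = grid[[bestIndex]], bestIndex = bestIndex, scores = scores)
}

#' Permutation-label validation of a classification pipeline
#'
#' Repeatedly shuffles the class labels (a pure permutation, preserving
#' class frequencies), re-runs stratified cross-validation on the
#' permuted labels, and records the mean macro F-measure of each
#' replicate. With the class signal destroyed, a sound pipeline scores at
#' chance level, far below its performance on the true labels.
#'
#' @param m a [GeneMatrix-class] or numeric matrix (with `labels`).
#' @param learner as in [crossValidate()].
#' @param nPerm number of label permutations.
#' @param seed integer master seed (permutation r uses a seed derived
#'   from it).
#' @param k,labels as in [crossValidate()].
#' @return list with `perPermutation` (numeric vector of mean macro-F
#'   values, length `nPerm`) and `grandMean` (their average; `NaN` when
#'   `nPerm = 0`).
#' @export
permutationValidation <- function(m, learner = ripperLearner(), nPerm = 100L,
                                  seed = 1L, k = 10L, labels = NULL) {
  if (is(m, "GeneMatrix")) {
    labels <- unname(classLabels(m))
    x <- matrixValues(m)
  } else {
    x <- as.matrix(m)
  }
  stopifnot(nPerm >= 0L)
  labels <- as.character(labels)
  res <- vapply(seq_len(nPerm), function(r) {
    perm <- withSeed(deriveSeed(seed, r), sample.int(length(labels)))
    crossValidate(x, learner, k = k, seed = deriveSeed(seed, r + nPerm),
                  labels = labels[perm])$meanMacroF
  }, numeric(1L))
  list(perPermutation = res, grandMean = mean(res))
}
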
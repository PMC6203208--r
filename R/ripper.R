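#' Sequential-covering threshold rule learner
#'
#' Learns an ordered rule model in the RIPPER/IREP family for a binary
#' classification problem over numeric features with possible missing
#' values. Rules are grown for the minority class (ties broken toward the
#' lexicographically first class label); the default class is the
#' majority class.
#'
#' One rule is built per outer iteration: the remaining training samples
#' are split (stratified, seeded) into a growing set and a pruning set —
#' the pruning set holds `1/pruneFolds` of the samples, mirroring
#' reduced-error pruning with that number of folds; the rule is grown
#' greedily, at each step adding the single condition
#' `feature <= t` / `feature >= t` (candidate thresholds are the midpoints
#' of consecutive distinct sorted feature values among the samples the
#' rule currently covers) that maximizes FOIL information gain; trailing
#' conditions are then pruned to maximize \eqn{(p - n) / (p + n)} on the
#' pruning set. Rule addition stops when no positives remain, when no
#' condition has positive gain, when the pruned rule's precision on the
#' pruning set drops below 0.5, or when the rule covers fewer than
#' `minCoverage` positive training samples. Covered samples are removed
#' and the next rule is grown.
#'
#' When the remaining data are too small for a meaningful split (fewer
#' than 9 samples or fewer than 3 members of either class), rules are
#' grown on all remaining samples without pruning and accepted if their
#' training precision is at least 0.5: reduced-error pruning is
#' uninformative on a handful of held-out samples.
#'
#' `optimizationRuns` extra restarts with re-drawn grow/prune splits are
#' performed and the ruleset with the best training macro F-measure is
#' kept (a repeat-and-keep-best stand-in for RIPPER's global optimization
#' passes).
#'
#' A condition on a missing value is not satisfied, so a rule never
#' covers a sample lacking one of its features.
#'
#' @param x numeric matrix (samples x features, `NA` allowed) or a
#'   [GeneMatrix-class].
#' @param y character vector of class labels (ignored when `x` is a
#'   `GeneMatrix`, whose labels are used).
#' @param pruneFolds integer; the pruning split holds `1/pruneFolds` of
#'   the samples (default 3, i.e. a 2:1 grow:prune split).
#' @param optimizationRuns integer number of keep-best restarts (default 2).
#' @param seed integer seed for the internal splits.
#' @param minCoverage minimum number of positive training samples a
#'   retained rule must cover (default 1).
#' @param maxRules,maxConditions safety caps on model size.
#' @return A [RuleModel-class].
#' @examples
#' x <- cbind(f = c(1, 2, 3, 10, 11))
#' y <- c("normal", "normal", "normal", "tumoral", "tumoral")
#' learnRuleset(x, y)
#' @export
learnRuleset <- function(x, y = NULL, pruneFolds = 3L, optimizationRuns = 2L,
                         seed = 1L, minCoverage = 1L, maxRules = 50L,
                         maxConditions = 10L) {
  if (is(x, "GeneMatrix")) {
    y <- unname(classLabels(x))
    x <- matrixValues(x)
  }
  stopifnot(is.matrix(x), !is.null(y), length(y) == nrow(x))
  storage.mode(x) <- "double"
  y <- as.character(y)
  if (anyNA(y)) stop("class labels must not be missing", call. = FALSE)
  classes <- sort(unique(y))
  if (length(classes) > 2L) {
    stop("only binary classification is supported", call. = FALSE)
  }
  if (length(classes) == 1L) {
    return(new("RuleModel", rules = list(), defaultClass = classes,
               trainFMeasure = 1))
  }
  if (nrow(x) < 4L) stop("need at least 4 samples", call. = FALSE)

  # ignore all-missing feature columns
  keep <- colSums(!is.na(x)) > 0L
  x <- x[, keep, drop = FALSE]
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))

  counts <- table(y)
  pos <- if (counts[[classes[1L]]] <= counts[[classes[2L]]]) classes[1L] else classes[2L]
  neg <- setdiff(classes, pos)

  best <- NULL
  for (run in seq_len(1L + max(0L, optimizationRuns))) {
    rules <- .irep(x, y == pos, pruneFolds = as.integer(pruneFolds),
                   seed = deriveSeed(seed, run), minCoverage = minCoverage,
                   maxRules = maxRules, maxConditions = maxConditions)
    model <- .asRuleModel(rules, colnames(x), pos, neg)
    f <- macroFMeasure(y, .predictRules(model, x))
    model@trainFMeasure <- f
    if (is.null(best) || f > best@trainFMeasure + 1e-12) best <- model
  }
  best
}

# Grow-and-prune loop over the remaining samples. `isPos` logical vector.
# Returns a list of rules, each a data.frame(feature=int, op, threshold).
.irep <- function(x, isPos, pruneFolds, seed, minCoverage, maxRules,
                  maxConditions) {
  remaining <- seq_len(nrow(x))
  rules <- list()
  splitCounter <- 0L
  while (sum(isPos[remaining]) > 0L && length(rules) < maxRules) {
    yr <- isPos[remaining]
    small <- length(remaining) < 15L || sum(yr) < 5L || sum(!yr) < 5L
    if (small) {
      growIdx <- remaining
      pruneIdx <- integer(0)
    } else {
      splitCounter <- splitCounter + 1L
      folds <- stratifiedFolds(ifelse(yr, "p", "n"), pruneFolds,
                               deriveSeed(seed, splitCounter))
      pruneIdx <- remaining[folds == 1L]
      growIdx <- remaining[folds != 1L]
      if (sum(isPos[growIdx]) == 0L) {
        growIdx <- remaining
        pruneIdx <- integer(0)
      }
    }
    cond <- .growRule(x, isPos, growIdx, maxConditions)
    if (is.null(cond)) break
    if (length(pruneIdx)) cond <- .pruneRule(cond, x, isPos, pruneIdx)

    # precision of the pruned rule on the pruning split (growing split
    # when the pruning split covers nothing or was not drawn)
    prec <- .rulePrecision(cond, x, isPos, pruneIdx)
    if (is.na(prec)) prec <- .rulePrecision(cond, x, isPos, growIdx)
    if (is.na(prec) || prec < 0.5) break

    covAll <- .ruleCoverage(cond, x, remaining)
    nPosCov <- sum(isPos[remaining][covAll])
    if (nPosCov < minCoverage || !any(covAll)) break
    rules[[length(rules) + 1L]] <- cond
    remaining <- remaining[!covAll]
  }
  rules
}

# Greedy FOIL-gain growth of one rule on rows `idx`. Conditions are
# data.frame(feature = column index, op, threshold).
.growRule <- function(x, isPos, idx, maxConditions) {
  covered <- idx
  conds <- data.frame(feature = integer(), op = character(),
                      threshold = numeric(), stringsAsFactors = FALSE)
  repeat {
    P0 <- sum(isPos[covered])
    N0 <- sum(!isPos[covered])
    if (P0 == 0L || N0 == 0L || nrow(conds) >= maxConditions) break
    baseLog <- log2(P0 / (P0 + N0))
    best <- NULL
    for (j in seq_len(ncol(x))) {
      cand <- .bestSplit(x[covered, j], isPos[covered], baseLog)
      if (!is.null(cand) && (is.null(best) || cand$gain > best$gain + 1e-12)) {
        best <- c(cand, list(feature = j))
      }
    }
    if (is.null(best) || best$gain <= 1e-9) break
    conds <- rbind(conds, data.frame(feature = best$feature, op = best$op,
                                     threshold = best$threshold,
                                     stringsAsFactors = FALSE))
    v <- x[covered, best$feature]
    keep <- if (best$op == "<=") !is.na(v) & v <= best$threshold else !is.na(v) & v >= best$threshold
    covered <- covered[keep]
  }
  if (nrow(conds)) conds else NULL
}

# Best single threshold condition on one feature by FOIL gain.
# Candidate thresholds are midpoints of consecutive distinct sorted
# values; ties prefer "<=" and then the smaller midpoint.
.bestSplit <- function(v, ip, baseLog) {
  ok <- !is.na(v)
  v <- v[ok]
  ip <- ip[ok]
  if (length(v) < 2L) return(NULL)
  o <- order(v, method = "radix")
  sv <- v[o]
  sp <- ip[o]
  b <- which(sv[-length(sv)] < sv[-1L])
  if (!length(b)) return(NULL)
  thr <- (sv[b] + sv[b + 1L]) / 2
  cp <- cumsum(sp)
  P <- cp[length(cp)]
  N <- length(sv) - P
  pLe <- cp[b]
  nLe <- b - pLe
  pGe <- P - pLe
  nGe <- N - nLe
  gainLe <- ifelse(pLe > 0, pLe * (log2(pLe / (pLe + nLe)) - baseLog), -Inf)
  gainGe <- ifelse(pGe > 0, pGe * (log2(pGe / (pGe + nGe)) - baseLog), -Inf)
  iLe <- which.max(gainLe)
  iGe <- which.max(gainGe)
  if (gainGe[iGe] > gainLe[iLe] + 1e-12) {
    list(gain = gainGe[iGe], op = ">=", threshold = thr[iGe])
  } else if (is.finite(gainLe[iLe])) {
    list(gain = gainLe[iLe], op = "<=", threshold = thr[iLe])
  } else {
    NULL
  }
}

# Reduced-error pruning: keep the prefix of conditions maximizing
# (p - n) / (p + n) on the pruning rows; ties keep the shorter prefix.
.pruneRule <- function(cond, x, isPos, pruneIdx) {
  K <- nrow(cond)
  if (K <= 1L) return(cond)
  cov <- rep(TRUE, length(pruneIdx))
  score <- numeric(K)
  for (k in seq_len(K)) {
    v <- x[pruneIdx, cond$feature[k]]
    sat <- if (cond$op[k] == "<=") !is.na(v) & v <= cond$threshold[k] else !is.na(v) & v >= cond$threshold[k]
    cov <- cov & sat
    p <- sum(isPos[pruneIdx][cov])
    n <- sum(cov) - p
    score[k] <- if (p + n > 0L) (p - n) / (p + n) else -Inf
  }
  kBest <- which.max(score)
  if (!is.finite(score[kBest])) return(cond)
  cond[seq_len(kBest), , drop = FALSE]
}

.ruleCoverage <- function(cond, x, idx) {
  cov <- rep(TRUE, length(idx))
  for (k in seq_len(nrow(cond))) {
    v <- x[idx, cond$feature[k]]
    sat <- if (cond$op[k] == "<=") !is.na(v) & v <= cond$threshold[k] else !is.na(v) & v >= cond$threshold[k]
    cov <- cov & sat
  }
  cov
}

.rulePrecision <- function(cond, x, isPos, idx) {
  if (!length(idx)) return(NA_real_)
  cov <- .ruleCoverage(cond, x, idx)
  tot <- sum(cov)
  if (tot == 0L) return(NA_real_)
  sum(isPos[idx][cov]) / tot
}

.asRuleModel <- function(rules, featureNames, pos, neg) {
  ruleObjs <- lapply(rules, function(cond) {
    new("Rule",
        conditions = data.frame(feature = featureNames[cond$feature],
                                op = cond$op, threshold = cond$threshold,
                                stringsAsFactors = FALSE),
        targetClass = pos)
  })
  new("RuleModel", rules = ruleObjs, defaultClass = neg, trainFMeasure = 0)
}

# first-match prediction over a samples x features matrix
.predictRules <- function(model, x) {
  pred <- rep(model@defaultClass, nrow(x))
  unassigned <- rep(TRUE, nrow(x))
  for (r in model@rules) {
    if (!any(unassigned)) break
    cov <- rep(TRUE, nrow(x))
    for (k in seq_len(nrow(r@conditions))) {
      f <- r@conditions$feature[k]
      if (!f %in% colnames(x)) {
        cov[] <- FALSE
        break
      }
      v <- x[, f]
      sat <- if (r@conditions$op[k] == "<=") !is.na(v) & v <= r@conditions$threshold[k] else !is.na(v) & v >= r@conditions$threshold[k]
      cov <- cov & sat
    }
    hit <- unassigned & cov
    pred[hit] <- r@targetClass
    unassigned <- unassigned & !cov
  }
  pred
}

#' Does a rule cover a sample?
#'
#' A rule covers a sample when every condition of its conjunction is
#' satisfied. A condition on a missing (or absent) feature value is not
#' satisfied. The empty conjunction covers every sample.
#'
#' @param rule a [Rule-class].
#' @param sample named numeric vector (or single-row data.frame/list) of
#'   feature values.
#' @return logical(1).
#' @rdname covers
#' @export
setMethod("covers", signature(rule = "Rule", sample = "ANY"), function(rule, sample) {
  sample <- unlist(sample)
  for (k in seq_len(nrow(rule@conditions))) {
    f <- rule@conditions$feature[k]
    v <- if (f %in% names(sample)) as.numeric(sample[[f]]) else NA_real_
    if (is.na(v)) return(FALSE)
    sat <- if (rule@conditions$op[k] == "<=") v <= rule@conditions$threshold[k] else v >= rule@conditions$threshold[k]
    if (!sat) return(FALSE)
  }
  TRUE
})

#' Predict class labels with a rule model
#'
#' First-match semantics: a sample is assigned the target class of the
#' first rule that covers it, and the model's default class when no rule
#' does.
#'
#' @param object a [RuleModel-class].
#' @param newdata samples x features numeric matrix, data.frame, named
#'   vector (single sample), or [GeneMatrix-class].
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @export
setMethod("predict", "RuleModel", function(object, newdata, ...) {
  if (is(newdata, "GeneMatrix")) newdata <- matrixValues(newdata)
  if (is.null(dim(newdata))) {
    newdata <- matrix(as.numeric(newdata), nrow = 1L,
                      dimnames = list(NULL, names(newdata)))
  }
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  .predictRules(object, newdata)
})

#' Features appearing in a rule model
#'
#' @param model a [RuleModel-class].
#' @return character vector of the distinct feature names used by the
#'   model's rules (empty for an empty model).
#' @export
ruleFeatures <- function(model) {
  stopifnot(is(model, "RuleModel"))
  sort(unique(unlist(lapply(model@rules, function(r) r@conditions$feature),
                     use.names = FALSE)))
}

.renderRule <- function(r) {
  if (!nrow(r@conditions)) return(paste0("-> class=", r@targetClass))
  lhs <- paste(sprintf("(%s %s %g)", r@conditions$feature, r@conditions$op,
                       r@conditions$threshold), collapse = " and ")
  paste0(lhs, " -> class=", r@targetClass)
}

setMethod("show", "Rule", function(object) cat(.renderRule(object), "\n"))

setMethod("show", "RuleModel", function(object) {
  for (r in object@rules) cat(.renderRule(r), "\n")
  cat("-> class=", object@defaultClass, "\n", sep = "")
  cat(sprintf("Number of Rules: %d (training F-measure %.3f)\n",
              length(object@rules) + 1L, object@trainFMeasure))
})

#' Serialize / deserialize a rule model as JSON
#'
#' @param model a [RuleModel-class].
#' @param path file path.
#' @return `writeRuleModel` returns `path` invisibly; `readRuleModel`
#'   returns a [RuleModel-class].
#' @export
writeRuleModel <- function(model, path) {
  stopifnot(is(model, "RuleModel"))
  obj <- list(
    rules = lapply(model@rules, function(r) {
      list(conditions = r@conditions, class = r@targetClass)
    }),
    default = model@defaultClass,
    train_f = model@trainFMeasure
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeRuleModel
#' @export
readRuleModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  ruleList <- if (length(obj$rules)) {
    if (is.data.frame(obj$rules)) {
      lapply(seq_len(nrow(obj$rules)), function(i) {
        new("Rule", conditions = as.data.frame(obj$rules$conditions[[i]]),
            targetClass = obj$rules$class[[i]])
      })
    } else {
      lapply(obj$rules, function(r) {
        new("Rule", conditions = as.data.frame(r$conditions),
            targetClass = r$class)
      })
    }
  } else {
    list()
  }
  new("RuleModel", rules = ruleList, defaultClass = obj$default,
      trainFMeasure = as.numeric(obj$train_f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rule learner factory for cross-validation and iterative extraction
#'
#' Wraps [learnRuleset()] with fixed parameters into a learner object
#' with a `fit(x, y)` component, the pluggable-classifier contract used
#' by [crossValidate()], [tuneParameters()], [permutationValidation()]
#' and [runCamur()]. Any classifier exposing this contract (fit returning
#' an object with a `predict` method yielding class labels) can be
#' substituted.
#'
#' @param ... parameters forwarded to [learnRuleset()].
#' @return list of class `"omicsLearner"` with components `fit`, `name`
#'   and `params`.
#' @export
ripperLearner <- function(...) {
  params <- list(...)
  structure(list(
    fit = function(x, y) do.call(learnRuleset, c(list(x = x, y = y), params)),
    name = "ripper",
    params = params
  ), class = "omicsLearner")
}
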
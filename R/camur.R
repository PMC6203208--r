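#' Configuration for the iterative multi-model extraction
#'
#' @param mode `"standard"` (features of archived rules are removed
#'   permanently) or `"loose"` (combinations of previously used features
#'   are removed temporarily, one combination per iteration).
#' @param fThreshold minimum cross-validated F-measure for archiving a
#'   model (default 0.8).
#' @param maxIterations iteration cap (default 100).
#' @param maxTime wall-time cap in seconds (default 30 days).
#' @param seed integer master seed.
#' @param cvFolds folds of the per-iteration cross-validation (default 10).
#' @param ripperParams list of extra parameters for [learnRuleset()].
#' @return A [CamurConfig-class].
#' @export
camurConfig <- function(mode = c("loose", "standard"), fThreshold = 0.8,
                        maxIterations = 100L, maxTime = 30 * 24 * 3600,
                        seed = 1L, cvFolds = 10L, ripperParams = list()) {
  mode <- match.arg(mode)
  if (!is.numeric(fThreshold) || length(fThreshold) != 1L ||
      fThreshold <= 0 || fThreshold > 1) {
    stop("fThreshold must lie in (0, 1]", call. = FALSE)
  }
  new("CamurConfig", mode = mode, fThreshold = fThreshold,
      maxIterations = as.integer(maxIterations), maxTime = as.numeric(maxTime),
      seed = as.integer(seed), cvFolds = as.integer(cvFolds),
      ripperParams = ripperParams)
}

# Smallest untried elimination subset of `pool` (size-ascending,
# lexicographic within size) that intersects every archived rule-feature
# set. Subsets missing some archived set are discarded without consuming
# an iteration: the learner is deterministic given a feature set, so
# training without such a subset reproduces an already-archived model.
# `budget` bounds the number of candidates examined.
.nextElimination <- function(pool, archivedSets, tried, budget = 200000L) {
  pool <- sort(pool)
  examined <- 0L
  for (s in seq_along(pool)) {
    if (choose(length(pool), s) > budget - examined) return(NULL)
    combIdx <- utils::combn(length(pool), s, simplify = FALSE)
    for (ci in combIdx) {
      examined <- examined + 1L
      if (examined > budget) return(NULL)
      subset <- pool[ci]
      key <- paste(subset, collapse = "\x1f")
      if (!is.null(tried[[key]])) next
      hitsAll <- all(vapply(archivedSets, function(fs) {
        length(fs) == 0L || any(subset %in% fs)
      }, logical(1L)))
      if (hitsAll) return(subset)
    }
  }
  NULL
}

#' Iterative extraction of multiple rule-based models
#'
#' Repeatedly learns rule models on the data matrix, eliminating features
#' used by previously extracted models so that alternative models over
#' different genes are found, and archives every model whose
#' cross-validated macro F-measure reaches the configured threshold.
#'
#' Iteration 0 trains on all features; the model quality is the mean
#' macro F-measure over stratified k-fold cross-validation, and the model
#' archived is the refit on all samples. In **standard** mode every
#' feature appearing in an archived model's rules is then removed
#' permanently and training repeats on the remainder until the quality
#' falls below the threshold. In **loose** mode a pool of features seen
#' in archived rules is maintained and candidate elimination subsets of
#' the pool are tried one per iteration, enumerated by increasing size
#' and lexicographically within size; a candidate that does not intersect
#' the rule features of every archived model is skipped without training,
#' because removing it provably reproduces an already-archived model. A
#' model trained under a temporary elimination is archived only when its
#' quality reaches the threshold and its rule-feature set differs from
#' every archived model's.
#'
#' The run stops when quality falls below the threshold (standard mode),
#' when the iteration or time cap is hit, or when no untried candidate
#' remains (`"exhausted"`).
#'
#' @param x a [GeneMatrix-class] with two classes (or a numeric matrix;
#'   then pass `labels`).
#' @param config a [CamurConfig-class], see [camurConfig()].
#' @param labels class labels when `x` is a plain matrix.
#' @param verbose print one line per iteration.
#' @return A [CamurRun-class].
#' @rdname runCamur
#' @export
setMethod("runCamur", "ANY", function(x, config = camurConfig(), labels = NULL,
                                      verbose = FALSE) {
  if (is(x, "GeneMatrix")) {
    labels <- unname(classLabels(x))
    x <- matrixValues(x)
  }
  x <- as.matrix(x)
  stopifnot(!is.null(labels), length(labels) == nrow(x))
  validObject(config)
  labels <- as.character(labels)
  if (length(unique(labels)) != 2L) {
    stop("the iterative extraction requires a binary-class matrix", call. = FALSE)
  }

  t0 <- Sys.time()
  models <- list()
  archivedSets <- list()
  tried <- new.env(parent = emptyenv())
  pool <- character(0)
  iter <- 0L
  stopReason <- NULL
  eliminated <- character(0)   # current elimination (empty at iteration 0)
  permanentDrop <- character(0)

  repeat {
    if (as.numeric(difftime(Sys.time(), t0, units = "secs")) > config@maxTime) {
      stopReason <- "time_limit"
      break
    }
    dropNow <- union(permanentDrop, eliminated)
    feats <- setdiff(colnames(x), dropNow)
    if (!length(feats)) {
      stopReason <- "exhausted"
      break
    }
    xi <- x[, feats, drop = FALSE]
    iter <- iter + 1L
    learner <- do.call(ripperLearner,
                       c(config@ripperParams,
                         list(seed = deriveSeed(config@seed, iter))))
    cv <- crossValidate(xi, learner, k = config@cvFolds,
                        seed = deriveSeed(config@seed, iter + 10000L),
                        labels = labels)
    model <- learner$fit(xi, labels)
    feats_used <- ruleFeatures(model)
    quality <- cv$meanMacroF
    archived <- FALSE
    if (quality >= config@fThreshold && length(feats_used)) {
      novel <- !any(vapply(archivedSets, identical, logical(1L), y = feats_used))
      if (novel) {
        models[[length(models) + 1L]] <- list(model = model,
                                              eliminated = dropNow,
                                              cvFMeasure = quality)
        archivedSets[[length(archivedSets) + 1L]] <- feats_used
        pool <- sort(union(pool, feats_used))
        archived <- TRUE
      }
    }
    if (verbose) {
      message(sprintf("iteration %d: CV F = %.3f, %d rule feature(s), %s",
                      iter, quality, length(feats_used),
                      if (archived) "archived" else "not archived"))
    }

    if (iter >= config@maxIterations) {
      stopReason <- "max_iterations"
      break
    }

    if (config@mode == "standard") {
      if (!archived) {
        stopReason <- if (quality < config@fThreshold) "below_threshold" else "exhausted"
        break
      }
      permanentDrop <- union(permanentDrop, feats_used)
    } else {
      nxt <- .nextElimination(pool, archivedSets, tried)
      if (is.null(nxt)) {
        stopReason <- "exhausted"
        break
      }
      assign(paste(nxt, collapse = "\x1f"), TRUE, envir = tried)
      eliminated <- nxt
    }
  }

  new("CamurRun", models = models, iterationsExecuted = iter,
      stopReason = stopReason, config = config)
})

setMethod("show", "CamurRun", function(object) {
  cat(sprintf("CamurRun (%s mode): %d archived model(s) in %d iteration(s); stop: %s\n",
              object@config@mode, length(object@models),
              object@iterationsExecuted, object@stopReason))
  if (length(object@models)) {
    f <- vapply(object@models, `[[`, numeric(1L), "cvFMeasure")
    cat(sprintf("  CV F-measure range: %.3f - %.3f; %d distinct gene feature(s)\n",
                min(f), max(f), length(runFeatures(object))))
  }
})

#' Features used across all archived models of a run
#'
#' @param run a [CamurRun-class].
#' @return character vector of distinct rule features.
#' @export
runFeatures <- function(run) {
  stopifnot(is(run, "CamurRun"))
  sort(unique(unlist(lapply(run@models, function(m) ruleFeatures(m$model)),
                     use.names = FALSE)))
}

#' Summaries of an iterative extraction run
#'
#' Derives the knowledge-extraction tables from an archive of rule
#' models: the flat rule list, literal frequencies (how often each
#' (feature, operator) pair occurs across all rules), the conjunction
#' list, co-occurrence counts of unordered feature pairs within a
#' conjunction, and the overall gene/feature list.
#'
#' @param run a [CamurRun-class].
#' @return list with components `rule_list` (data.frame: model, rule,
#'   text, class), `literal_frequencies` (data.frame: feature, op,
#'   count), `conjunction_list` (data.frame: conjunction, class, count),
#'   `feature_pair_cooccurrence` (data.frame: feature1, feature2, count),
#'   `gene_list` (character).
#' @rdname analyzeRun
#' @export
setMethod("analyzeRun", "CamurRun", function(run) {
  ruleRows <- list()
  litKeys <- character(0)
  conjKeys <- character(0)
  conjClasses <- character(0)
  pairKeys <- character(0)
  for (mi in seq_along(run@models)) {
    model <- run@models[[mi]]$model
    for (ri in seq_along(model@rules)) {
      r <- model@rules[[ri]]
      ruleRows[[length(ruleRows) + 1L]] <-
        data.frame(model = mi, rule = ri, text = .renderRule(r),
                   class = r@targetClass, stringsAsFactors = FALSE)
      litKeys <- c(litKeys, paste(r@conditions$feature, r@conditions$op,
                                  sep = "\x1f"))
      conj <- paste(sprintf("(%s %s %g)", r@conditions$feature,
                            r@conditions$op, r@conditions$threshold),
                    collapse = " and ")
      conjKeys <- c(conjKeys, conj)
      conjClasses <- c(conjClasses, r@targetClass)
      feats <- sort(unique(r@conditions$feature))
      if (length(feats) >= 2L) {
        prs <- utils::combn(feats, 2L)
        pairKeys <- c(pairKeys, paste(prs[1L, ], prs[2L, ], sep = "\x1f"))
      }
    }
  }
  litTab <- if (length(litKeys)) {
    tb <- table(litKeys)
    parts <- strsplit(names(tb), "\x1f", fixed = TRUE)
    data.frame(feature = vapply(parts, `[`, character(1L), 1L),
               op = vapply(parts, `[`, character(1L), 2L),
               count = as.integer(tb), stringsAsFactors = FALSE)
  } else {
    data.frame(feature = character(), op = character(), count = integer())
  }
  conjTab <- if (length(conjKeys)) {
    key <- paste(conjKeys, conjClasses, sep = "\x1f\x1f")
    tb <- table(key)
    parts <- strsplit(names(tb), "\x1f\x1f", fixed = TRUE)
    data.frame(conjunction = vapply(parts, `[`, character(1L), 1L),
               class = vapply(parts, `[`, character(1L), 2L),
               count = as.integer(tb), stringsAsFactors = FALSE)
  } else {
    data.frame(conjunction = character(), class = character(), count = integer())
  }
  pairTab <- if (length(pairKeys)) {
    tb <- table(pairKeys)
    parts <- strsplit(names(tb), "\x1f", fixed = TRUE)
    data.frame(feature1 = vapply(parts, `[`, character(1L), 1L),
               feature2 = vapply(parts, `[`, character(1L), 2L),
               count = as.integer(tb), stringsAsFactors = FALSE)
  } else {
    data.frame(feature1 = character(), feature2 = character(), count = integer())
  }
  list(
    rule_list = if (length(ruleRows)) do.call(rbind, ruleRows) else
      data.frame(model = integer(), rule = integer(), text = character(),
                 class = character(), stringsAsFactors = FALSE),
    literal_frequencies = litTab,
    conjunction_list = conjTab,
    feature_pair_cooccurrence = pairTab,
    gene_list = runFeatures(run)
  )
})

#' Serialize / deserialize a CamurRun as JSON
#'
#' @param run a [CamurRun-class].
#' @param path file path.
#' @return `writeCamurRun` returns `path` invisibly; `readCamurRun`
#'   returns a [CamurRun-class].
#' @export
writeCamurRun <- function(run, path) {
  stopifnot(is(run, "CamurRun"))
  cfg <- run@config
  obj <- list(
    config = list(mode = cfg@mode, f_threshold = cfg@fThreshold,
                  max_iterations = cfg@maxIterations, max_time = cfg@maxTime,
                  seed = cfg@seed, cv_folds = cfg@cvFolds),
    iterations_executed = run@iterationsExecuted,
    stop_reason = run@stopReason,
    models = lapply(run@models, function(m) {
      list(
        rules = lapply(m$model@rules, function(r) {
          list(conditions = r@conditions, class = r@targetClass)
        }),
        default = m$model@defaultClass,
        train_f = m$model@trainFMeasure,
        cv_f = m$cvFMeasure,
        eliminated = as.list(m$eliminated)
      )
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeCamurRun
#' @export
readCamurRun <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- camurConfig(mode = obj$config$mode, fThreshold = obj$config$f_threshold,
                     maxIterations = obj$config$max_iterations,
                     maxTime = obj$config$max_time, seed = obj$config$seed,
                     cvFolds = obj$config$cv_folds)
  models <- lapply(obj$models, function(m) {
    rules <- lapply(m$rules, function(r) {
      cond <- do.call(rbind, lapply(r$conditions, as.data.frame))
      cond$feature <- as.character(cond$feature)
      cond$op <- as.character(cond$op)
      cond$threshold <- as.numeric(cond$threshold)
      new("Rule", conditions = cond, targetClass = r$class)
    })
    list(model = new("RuleModel", rules = rules, defaultClass = m$default,
                     trainFMeasure = as.numeric(m$train_f)),
         eliminated = as.character(unlist(m$eliminated)),
         cvFMeasure = as.numeric(m$cv_f))
  })
  new("CamurRun", models = models, iterationsExecuted = obj$iterations_executed,
      stopReason = obj$stop_reason, config = cfg)
}
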
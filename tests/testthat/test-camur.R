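# A dataset where three features carry the same (perfect) class signal,
# so iterative extraction must find several alternative models.
redundantDataset <- function(seed = 17, n = 40L) {
  set.seed(seed)
  signal <- c(runif(n / 2, 0, 1), runif(n / 2, 2, 3))
  x <- cbind(f1 = signal + rnorm(n, sd = 0.05),
             f2 = signal + rnorm(n, sd = 0.05),
             f3 = signal + rnorm(n, sd = 0.05),
             n1 = rnorm(n), n2 = rnorm(n))
  y <- rep(c("normal", "tumoral"), each = n / 2)
  list(x = x, y = y)
}

test_that("loose mode extracts one model per redundant signal feature", {
  d <- redundantDataset()
  run <- runCamur(d$x, camurConfig("loose", fThreshold = 0.8, seed = 5,
                                   cvFolds = 5, maxIterations = 50),
                  labels = d$y)
  expect_gte(length(run@models), 3L)
  expect_true(all(c("f1", "f2", "f3") %in% runFeatures(run)))
  # archived feature sets are pairwise distinct (novelty requirement)
  sets <- lapply(run@models, function(m) ruleFeatures(m$model))
  keys <- vapply(sets, paste, character(1L), collapse = "|")
  expect_identical(anyDuplicated(keys), 0L)
  # every archived model clears the threshold
  f <- vapply(run@models, `[[`, numeric(1L), "cvFMeasure")
  expect_true(all(f >= 0.8))
  expect_true(run@stopReason %in%
                c("exhausted", "max_iterations", "below_threshold"))
})

test_that("standard mode removes archived features permanently", {
  d <- redundantDataset(seed = 23)
  run <- runCamur(d$x, camurConfig("standard", fThreshold = 0.8, seed = 2,
                                   cvFolds = 5, maxIterations = 50),
                  labels = d$y)
  expect_gte(length(run@models), 2L)
  sets <- lapply(run@models, function(m) ruleFeatures(m$model))
  # feature sets of successive models are pairwise disjoint
  for (i in seq_along(sets)) for (j in seq_len(i - 1L)) {
    expect_length(intersect(sets[[i]], sets[[j]]), 0L)
  }
  # once the noise features are all that remains, quality collapses
  expect_identical(run@stopReason, "below_threshold")
})

test_that("the iteration cap stops the run after exactly one iteration", {
  d <- redundantDataset()
  run <- runCamur(d$x, camurConfig("loose", maxIterations = 1, seed = 5,
                                   cvFolds = 5), labels = d$y)
  expect_identical(run@iterationsExecuted, 1L)
  expect_identical(run@stopReason, "max_iterations")
  expect_lte(length(run@models), 1L)
})

test_that("runs are reproducible under the same seed", {
  d <- redundantDataset()
  cfg <- camurConfig("loose", fThreshold = 0.8, seed = 9, cvFolds = 5,
                     maxIterations = 20)
  r1 <- runCamur(d$x, cfg, labels = d$y)
  r2 <- runCamur(d$x, cfg, labels = d$y)
  expect_identical(r1@iterationsExecuted, r2@iterationsExecuted)
  expect_identical(r1@stopReason, r2@stopReason)
  expect_equal(r1@models, r2@models)
})

test_that("elimination candidates hit every archived model and skip duplicates", {
  # archived sets {a,b} and {c}: a hitting subset must touch both
  got <- ruleOmics:::.nextElimination(
    pool = c("a", "b", "c"),
    archivedSets = list(c("a", "b"), "c"),
    tried = new.env(parent = emptyenv()))
  # no singleton hits both sets; the first size-2 lexicographic hit is {a,c}
  expect_identical(got, c("a", "c"))
  tried <- new.env(parent = emptyenv())
  assign(paste(c("a", "c"), collapse = "\x1f"), TRUE, envir = tried)
  expect_identical(ruleOmics:::.nextElimination(
    c("a", "b", "c"), list(c("a", "b"), "c"), tried), c("b", "c"))
  # nothing left once all hitting subsets are tried
  for (k in list(c("b", "c"), c("a", "b", "c"))) {
    assign(paste(k, collapse = "\x1f"), TRUE, envir = tried)
  }
  expect_null(ruleOmics:::.nextElimination(
    c("a", "b", "c"), list(c("a", "b"), "c"), tried))
})

# A hand-built two-model archive for the counting summaries.
handRun <- function() {
  r1 <- new("Rule", conditions = data.frame(
    feature = c("GDA_rnaSeq", "SCN3A_dnaMeth"), op = c("<=", ">="),
    threshold = c(1.5, 2), stringsAsFactors = FALSE), targetClass = "normal")
  r2 <- new("Rule", conditions = data.frame(
    feature = "GDA_rnaSeq", op = "<=", threshold = 9,
    stringsAsFactors = FALSE), targetClass = "normal")
  m1 <- new("RuleModel", rules = list(r1, r2), defaultClass = "tumoral",
            trainFMeasure = 0.9)
  m2 <- new("RuleModel", rules = list(r1), defaultClass = "tumoral",
            trainFMeasure = 0.85)
  new("CamurRun",
      models = list(list(model = m1, eliminated = character(0),
                         cvFMeasure = 0.9),
                    list(model = m2, eliminated = "X", cvFMeasure = 0.85)),
      iterationsExecuted = 2L, stopReason = "exhausted",
      config = camurConfig("loose"))
}

test_that("run summaries match a hand tally, including duplicated rules", {
  an <- analyzeRun(handRun())
  expect_equal(nrow(an$rule_list), 3L)
  expect_identical(an$gene_list, sort(c("GDA_rnaSeq", "SCN3A_dnaMeth")))
  # literal (feature, op) tallies: GDA <= appears in all three rules,
  # SCN3A >= in the duplicated conjunction (2 models)
  lf <- an$literal_frequencies
  expect_identical(lf$count[lf$feature == "GDA_rnaSeq" & lf$op == "<="], 3L)
  expect_identical(lf$count[lf$feature == "SCN3A_dnaMeth" & lf$op == ">="], 2L)
  # the two-condition conjunction occurs twice, the singleton once
  cj <- an$conjunction_list
  expect_identical(sort(cj$count), c(1L, 2L))
  expect_equal(sum(cj$count), nrow(an$rule_list))
  # one unordered feature pair, co-occurring twice
  pr <- an$feature_pair_cooccurrence
  expect_equal(nrow(pr), 1L)
  expect_identical(pr$count, 2L)
  expect_true(pr$feature1 < pr$feature2)
})

test_that("an empty archive yields empty summaries", {
  empty <- new("CamurRun", models = list(), iterationsExecuted = 0L,
               stopReason = "below_threshold", config = camurConfig())
  an <- analyzeRun(empty)
  expect_identical(nrow(an$rule_list), 0L)
  expect_identical(nrow(an$literal_frequencies), 0L)
  expect_length(an$gene_list, 0L)
  expect_length(runFeatures(empty), 0L)
})

test_that("a run survives a JSON round-trip", {
  run <- handRun()
  p <- tempfile(fileext = ".json")
  writeCamurRun(run, p)
  back <- readCamurRun(p)
  expect_identical(back@stopReason, run@stopReason)
  expect_identical(back@iterationsExecuted, run@iterationsExecuted)
  expect_length(back@models, 2L)
  expect_equal(back@models[[1]]$model@rules[[1]]@conditions,
               run@models[[1]]$model@rules[[1]]@conditions)
  expect_identical(back@models[[2]]$eliminated, "X")
  expect_equal(analyzeRun(back), analyzeRun(run))
})
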
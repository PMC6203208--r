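test_that("rule coverage is conjunctive and missing values block coverage", {
  r <- exampleRuleModel()@rules[[1]]
  expect_true(covers(r, c(MAP3K11_dnaMeth = 10, PIP5KL1_dnaMeth = 3)))
  expect_false(covers(r, c(MAP3K11_dnaMeth = 13, PIP5KL1_dnaMeth = 3)))
  expect_false(covers(r, c(MAP3K11_dnaMeth = 10, PIP5KL1_dnaMeth = NA)))
  expect_false(covers(r, c(MAP3K11_dnaMeth = 10)))   # feature absent
  # boundary values satisfy <= / >=
  expect_true(covers(r, c(MAP3K11_dnaMeth = 12.3, PIP5KL1_dnaMeth = 2.1)))
  empty <- new("Rule", conditions = data.frame(feature = character(),
                                               op = character(),
                                               threshold = numeric()),
               targetClass = "normal")
  expect_true(covers(empty, c(whatever = 1)))
})

test_that("prediction is first-match with default fallback", {
  m <- exampleRuleModel()
  expect_identical(predict(m, c(MAP3K11_dnaMeth = 12.0, PIP5KL1_dnaMeth = 2.5)),
                   "normal")
  expect_identical(predict(m, c(MAP3K11_dnaMeth = 20.0, PIP5KL1_dnaMeth = 2.5)),
                   "tumoral")
  noRules <- new("RuleModel", rules = list(), defaultClass = "tumoral",
                 trainFMeasure = 1)
  x <- matrix(rnorm(10), 5, dimnames = list(NULL, c("a", "b")))
  expect_identical(predict(noRules, x), rep("tumoral", 5))
})

test_that("a clean 1-D gap is separated perfectly with one threshold rule", {
  x <- cbind(f = c(1, 2, 3, 10, 11))
  y <- c(rep("normal", 3), rep("tumoral", 2))
  m <- learnRuleset(x, y, seed = 1)
  pred <- predict(m, x)
  expect_identical(pred, y)
  # the threshold sits in the gap
  thr <- m@rules[[1]]@conditions$threshold
  expect_true(thr > 3 && thr < 10)
  # matches the exhaustively best single rule (accuracy 1)
  expect_equal(mean(pred == y), bestSingleRuleAccuracy(x, y))
})

test_that("degenerate inputs give degenerate models", {
  x <- matrix(rnorm(12), 6, dimnames = list(NULL, c("a", "b")))
  m <- learnRuleset(x, rep("tumoral", 6))
  expect_length(m@rules, 0L)
  expect_identical(m@defaultClass, "tumoral")
  expect_error(learnRuleset(x, c("a", "b", "c", "a", "b", "c")), "binary")
  # all-missing feature columns are ignored
  x2 <- cbind(f = c(1, 2, 3, 10, 11, 12), g = NA_real_)
  y2 <- rep(c("normal", "tumoral"), each = 3)
  m2 <- learnRuleset(x2, y2, seed = 3)
  expect_false("g" %in% ruleFeatures(m2))
  expect_identical(predict(m2, x2), y2)
})

test_that("training accuracy dominates the exhaustive single-rule oracle on tiny data", {
  for (seed in 1:30) {
    d <- tinyDataset(seed, n = sample(6:12, 1), p = 2L)
    m <- learnRuleset(d$x, d$y, seed = seed)
    acc <- mean(predict(m, d$x) == d$y)
    expect_gte(acc, bestSingleRuleAccuracy(d$x, d$y))
  }
})

test_that("a planted pure conjunction is recovered on separable 2-D data", {
  set.seed(5)
  # positives live in the upper-left quadrant (f1 <= 0, f2 >= 0)
  x <- cbind(f1 = runif(40, -1, 1), f2 = runif(40, -1, 1))
  y <- ifelse(x[, 1] <= 0 & x[, 2] >= 0, "normal", "tumoral")
  stopifnot(sum(y == "normal") >= 5)
  m <- learnRuleset(x, y, seed = 2)
  pred <- predict(m, x)
  planted <- bestPureConjunctionCover(x, y, "normal")
  # the learner's covered set equals the planted positive set
  expect_identical(pred == "normal", unname(planted))
  expect_identical(unname(pred), unname(y))
})

test_that("the learner is deterministic and reports a verifiable training F", {
  set.seed(11)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- ifelse(x[, 2] + rnorm(50, sd = 0.4) > 0, "tumoral", "normal")
  m1 <- learnRuleset(x, y, seed = 9)
  m2 <- learnRuleset(x, y, seed = 9)
  expect_equal(m1, m2)
  expect_equal(m1@trainFMeasure, macroFMeasure(y, predict(m1, x)),
               tolerance = 1e-12)
})

test_that("retained rules respect the minimum positive coverage", {
  set.seed(21)
  x <- matrix(rnorm(300), 75, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- ifelse(x[, 1] > 0.2, "tumoral", "normal")
  m <- learnRuleset(x, y, seed = 4, minCoverage = 5L)
  for (r in m@rules) {
    cov <- vapply(seq_len(nrow(x)), function(i) covers(r, x[i, ]), logical(1))
    expect_gte(sum(cov & y == r@targetClass), 5L)
  }
})

test_that("rule models survive a JSON round-trip and render readably", {
  m <- exampleRuleModel()
  p <- tempfile(fileext = ".json")
  writeRuleModel(m, p)
  back <- readRuleModel(p)
  expect_equal(back@rules[[1]]@conditions, m@rules[[1]]@conditions)
  expect_identical(back@defaultClass, m@defaultClass)
  expect_equal(back@trainFMeasure, m@trainFMeasure)
  txt <- capture.output(show(m))
  expect_match(txt[1], "\\(MAP3K11_dnaMeth <= 12.3\\) and \\(PIP5KL1_dnaMeth >= 2.1\\) -> class=normal")
  expect_match(txt[2], "class=tumoral")
})
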
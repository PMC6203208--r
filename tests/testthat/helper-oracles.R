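# Independent brute-force oracles used to check the learner and the
# set/counting operations.

# Training accuracy of the best single-condition rule (feature, op,
# midpoint threshold, either class as target, default = other class),
# found by exhaustive search.
bestSingleRuleAccuracy <- function(x, y) {
  classes <- sort(unique(y))
  best <- max(table(y)) / length(y)   # empty model: majority default
  for (j in seq_len(ncol(x))) {
    v <- sort(unique(x[, j]))
    if (length(v) < 2L) next
    thrs <- (v[-1L] + v[-length(v)]) / 2
    for (t in thrs) for (op in c("<=", ">=")) {
      cov <- if (op == "<=") x[, j] <= t else x[, j] >= t
      for (target in classes) {
        other <- setdiff(classes, target)
        pred <- ifelse(cov, target, other[1L])
        best <- max(best, mean(pred == y))
      }
    }
  }
  best
}

# Covered set of the best two-condition conjunction (exhaustive over
# ordered pairs of midpoint-threshold conditions) that covers only
# positives and the most of them.
bestPureConjunctionCover <- function(x, y, positive) {
  n <- nrow(x)
  conds <- list()
  for (j in seq_len(ncol(x))) {
    v <- sort(unique(x[, j]))
    if (length(v) < 2L) next
    for (t in (v[-1L] + v[-length(v)]) / 2) {
      conds[[length(conds) + 1L]] <- list(j = j, t = t, le = TRUE)
      conds[[length(conds) + 1L]] <- list(j = j, t = t, le = FALSE)
    }
  }
  covOf <- function(cc) if (cc$le) x[, cc$j] <= cc$t else x[, cc$j] >= cc$t
  best <- rep(FALSE, n)
  for (a in conds) for (b in conds) {
    cov <- covOf(a) & covOf(b)
    if (any(cov & y != positive)) next
    if (sum(cov) > sum(best)) best <- cov
  }
  best
}

# Venn region counts by per-element membership tally.
bruteVennCounts <- function(sets) {
  nm <- names(sets)
  universe <- unique(unlist(sets))
  key <- vapply(universe, function(g) {
    paste(nm[vapply(sets, function(s) g %in% s, logical(1L))], collapse = "&")
  }, character(1L))
  table(key)
}

# The printed example matrices of the worked breast-cancer join. Class
# labels are passed explicitly (the example tables are illustrative).
exampleRnaMatrix <- function() {
  GeneMatrix(
    matrix(c(0.6, 0.0, 28.4, 6.4, 43.6, 1.9), nrow = 2,
           dimnames = list(c("TCGA-A1-A0SD-01A-11R-A115-07",
                             "TCGA-A7-A4SD-01A-11R-A266-07"),
                           c("GDA", "SCN3A", "SCN3B"))),
    classLabels = c("normal", "tumoral"), experimentTag = "rnaSeq")
}

exampleMethMatrix <- function() {
  GeneMatrix(
    matrix(c(1.6, 1.9, 2.3, 2.7, 2.0, 2.3), nrow = 2,
           dimnames = list(c("TCGA-A7-A4SD-01A-11D-A268-05",
                             "TCGA-GI-A2C9-01A-11D-A21R-05"),
                           c("GDA", "SCN3A", "SCN3B"))),
    classLabels = c("tumoral", "tumoral"), experimentTag = "dnaMeth")
}

# The published two-rule kidney-cancer methylation model:
# (MAP3K11_dnaMeth <= 12.3) and (PIP5KL1_dnaMeth >= 2.1) -> normal,
# default tumoral.
exampleRuleModel <- function() {
  new("RuleModel",
      rules = list(new("Rule",
                       conditions = data.frame(
                         feature = c("MAP3K11_dnaMeth", "PIP5KL1_dnaMeth"),
                         op = c("<=", ">="), threshold = c(12.3, 2.1),
                         stringsAsFactors = FALSE),
                       targetClass = "normal")),
      defaultClass = "tumoral", trainFMeasure = 0.95)
}

# random tiny binary dataset for oracle-equivalence checks
tinyDataset <- function(seed, n = 10L, p = 2L) {
  set.seed(seed)
  x <- matrix(round(stats::rnorm(n * p), 2), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- sample(c("normal", "tumoral"), n, replace = TRUE)
  if (length(unique(y)) == 1L) y[1L] <- setdiff(c("normal", "tumoral"), y[1L])
  list(x = x, y = y)
}
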
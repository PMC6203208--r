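test_that("gene methylation quantity is the sum of a gene's site betas", {
  recs <- data.frame(gene = c("GDA", "GDA", "GDA", "SCN3A"),
                     beta = c(0.4, 0.7, 0.5, 0.9))
  agg <- aggregateMethylation(recs)
  expect_equal(unname(agg["GDA"]), 1.6)
  expect_equal(unname(agg["SCN3A"]), 0.9)

  # one site with beta 0 keeps the gene present at value 0
  agg0 <- aggregateMethylation(data.frame(gene = "X", beta = 0))
  expect_identical(unname(agg0["X"]), 0)

  # empty input, missing betas and unannotated sites are dropped
  expect_length(aggregateMethylation(data.frame(gene = character(),
                                                beta = numeric())), 0L)
  agg2 <- aggregateMethylation(data.frame(gene = c("A", "A", ""),
                                          beta = c(0.2, NA, 0.9)))
  expect_equal(unname(agg2["A"]), 0.2)
  expect_false("" %in% names(agg2))
})

test_that("aggregation matches a fold-by-addition oracle on random betas", {
  set.seed(101)
  for (rep in 1:5) {
    genes <- sample(paste0("G", 1:8), 50, replace = TRUE)
    betas <- runif(50)
    agg <- aggregateMethylation(data.frame(gene = genes, beta = betas))
    for (g in unique(genes)) {
      acc <- 0
      for (b in betas[genes == g]) acc <- acc + b
      expect_equal(unname(agg[g]), acc, tolerance = 1e-12)
    }
    # conservation: total quantity equals total annotated beta mass
    expect_equal(sum(agg), sum(betas), tolerance = 1e-12)
  }
})

test_that("aggregation is permutation-invariant and monotone in added sites", {
  set.seed(102)
  recs <- data.frame(gene = sample(c("A", "B", "C"), 30, replace = TRUE),
                     beta = runif(30))
  base <- aggregateMethylation(recs)
  for (i in 1:5) {
    perm <- recs[sample.int(nrow(recs)), ]
    expect_identical(aggregateMethylation(perm), base)
  }
  more <- rbind(recs, data.frame(gene = "B", beta = 0.3))
  expect_gt(aggregateMethylation(more)[["B"]], base[["B"]])
})

test_that("composite gene annotations contribute to every listed gene", {
  agg <- aggregateMethylation(data.frame(gene = c("A;B", "B"),
                                         beta = c(0.5, 0.2)))
  expect_equal(unname(agg["A"]), 0.5)
  expect_equal(unname(agg["B"]), 0.7)
})

test_that("matrix assembly takes the sorted gene union with missing fill", {
  per <- list(S2 = c(B = 2, C = 3), S1 = c(A = 1, B = 9))
  m <- buildGeneMatrix(per, labels = c(S1 = "normal", S2 = "tumoral"),
                       experimentTag = "rnaSeq")
  expect_identical(featureIDs(m), c("A", "B", "C"))
  expect_identical(sampleIDs(m), c("S1", "S2"))
  vals <- matrixValues(m)
  expect_true(is.na(vals["S1", "C"]))
  expect_true(is.na(vals["S2", "A"]))
  expect_equal(vals["S1", "B"], 9)
  expect_error(buildGeneMatrix(per, labels = c(S1 = "normal"),
                               experimentTag = "rnaSeq"), "S2")

  z <- buildGeneMatrix(list(), labels = character(0), experimentTag = "dnaMeth")
  expect_equal(dim(matrixValues(z)), c(0L, 0L))

  m0 <- buildGeneMatrix(per, labels = c(S1 = "normal", S2 = "tumoral"),
                        experimentTag = "rnaSeq", fill = 0)
  expect_equal(matrixValues(m0)["S1", "C"], 0)
})

test_that("the printed expression example reassembles cell-for-cell", {
  per <- list(
    "TCGA-A1-A0SD-01A-11R-A115-07" = c(GDA = 0.6, SCN3A = 28.4, SCN3B = 43.6),
    "TCGA-A7-A4SD-01A-11R-A266-07" = c(GDA = 0.0, SCN3A = 6.4, SCN3B = 1.9))
  labels <- c("TCGA-A1-A0SD-01A-11R-A115-07" = "normal",
              "TCGA-A7-A4SD-01A-11R-A266-07" = "tumoral")
  m <- buildGeneMatrix(per, labels, experimentTag = "rnaSeq")
  expect_equal(matrixValues(m),
               matrixValues(exampleRnaMatrix()))
  expect_identical(unname(classLabels(m)), c("normal", "tumoral"))
})

test_that("CSV round-trip preserves values, missing entries and labels", {
  vals <- matrix(c(1.25, NA, 3, 4.5, 5, 6), nrow = 3,
                 dimnames = list(paste0("TCGA-XX-A00", 1:3, "-01A"),
                                 c("G1", "G2")))
  m <- GeneMatrix(vals, classLabels = c("tumoral", "normal", "tumoral"),
                  experimentTag = "dnaMeth")
  p <- tempfile(fileext = ".csv")
  writeGeneMatrix(m, p)
  lines <- readLines(p)
  expect_identical(lines[1], "Sample_ID,G1,G2,Class")
  expect_match(lines[3], "\\?")   # missing rendered as ?
  back <- readGeneMatrix(p, "dnaMeth")
  expect_equal(matrixValues(back), matrixValues(m))
  expect_identical(classLabels(back), classLabels(m))
  expect_identical(experimentTag(back), "dnaMeth")
})

test_that("ragged or mislabeled matrix CSVs are rejected", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("Sample_ID,G1,G2,Class", "S1,1,2,normal", "S2,1,tumoral"), p)
  expect_error(readGeneMatrix(p, "rnaSeq"))
  p2 <- tempfile(fileext = ".csv")
  writeLines(c("G1,G2", "1,2"), p2)
  expect_error(readGeneMatrix(p2, "rnaSeq"), "Sample_ID")
})
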
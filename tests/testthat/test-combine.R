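test_that("combining keeps each input namespace intact and verbatim", {
  cm <- combineMatrices(exampleMethMatrix(), exampleRnaMatrix())
  expect_identical(experimentTag(cm), "combined")
  # width is the exact sum of the input widths
  expect_length(featureIDs(cm), 6L)
  expect_identical(featureIDs(cm),
                   c("GDA_dnaMeth", "SCN3A_dnaMeth", "SCN3B_dnaMeth",
                     "GDA_rnaSeq", "SCN3A_rnaSeq", "SCN3B_rnaSeq"))
  vals <- matrixValues(cm)
  # shared sample carries both blocks verbatim
  expect_equal(vals["TCGA-A7-A4SD-01A", c("GDA_dnaMeth", "SCN3A_dnaMeth")],
               c(GDA_dnaMeth = 1.6, SCN3A_dnaMeth = 2.3))
  expect_equal(vals["TCGA-A7-A4SD-01A", c("GDA_rnaSeq", "SCN3A_rnaSeq")],
               c(GDA_rnaSeq = 0.0, SCN3A_rnaSeq = 6.4))
  # single-experiment samples have the other block fully missing
  expect_true(all(is.na(vals["TCGA-A1-A0SD-01A", 1:3])))
  expect_true(all(is.na(vals["TCGA-GI-A2C9-01A", 4:6])))
})

test_that("combining an empty partner yields the other matrix, suffixed", {
  empty <- buildGeneMatrix(list(), labels = character(0),
                           experimentTag = "dnaMeth")
  cm <- combineMatrices(empty, exampleRnaMatrix())
  expect_identical(featureIDs(cm), paste0(c("GDA", "SCN3A", "SCN3B"), "_rnaSeq"))
  expect_equal(unname(matrixValues(cm)["TCGA-A1-A0SD-01A", "SCN3A_rnaSeq"]), 28.4)
  expect_identical(unname(classLabels(cm)), c("normal", "tumoral"))
})

test_that("row counts follow the outer-join arithmetic on generated IDs", {
  set.seed(7)
  for (rep in 1:5) {
    a <- sample(1:6, 1); b <- sample(1:6, 1); c <- sample(1:6, 1)
    ids <- sprintf("TCGA-SY-A%03d-01A", seq_len(a + b + c))
    methIDs <- ids[seq_len(a + c)]                      # a exclusive + c shared
    rnaIDs <- ids[c(seq_len(c), a + c + seq_len(b))]    # c shared + b exclusive
    meth <- buildGeneMatrix(stats::setNames(lapply(methIDs, function(i) c(G1 = 1)),
                                            paste0(methIDs, "-11D-A001-05")),
                            stats::setNames(rep("tumoral", a + c),
                                            paste0(methIDs, "-11D-A001-05")),
                            "dnaMeth")
    rna <- buildGeneMatrix(stats::setNames(lapply(rnaIDs, function(i) c(G1 = 2)),
                                           paste0(rnaIDs, "-11R-A001-07")),
                           stats::setNames(rep("tumoral", b + c),
                                           paste0(rnaIDs, "-11R-A001-07")),
                           "rnaSeq")
    cm <- combineMatrices(meth, rna)
    expect_length(sampleIDs(cm), a + b + c)
    vals <- matrixValues(cm)
    complete <- rowSums(is.na(vals)) == 0L
    expect_equal(sum(complete), c)
    expect_length(sampleIDs(combineMatrices(meth, rna, completeCases = TRUE)), c)
  }
})

test_that("combination is symmetric in information content", {
  ab <- combineMatrices(exampleMethMatrix(), exampleRnaMatrix())
  ba <- combineMatrices(exampleMethMatrix(), exampleRnaMatrix())
  reordered <- matrixValues(ba)[, featureIDs(ab)]
  expect_equal(matrixValues(ab), reordered)
})

test_that("conflicting labels and duplicate truncated IDs are errors", {
  # the same truncated sample labeled tumoral in one experiment and
  # normal in the other
  meth <- GeneMatrix(matrix(3.8, 1, dimnames =
                              list("TCGA-3C-AALK-01A-11D-A41Q-05", "GDA")),
                     "normal", "dnaMeth")
  rna <- GeneMatrix(matrix(0.0, 1, dimnames =
                             list("TCGA-3C-AALK-01A-11R-A41B-07", "GDA")),
                    "tumoral", "rnaSeq")
  expect_error(combineMatrices(meth, rna), "conflicting class labels")

  # two aliquots of the same sample within one experiment
  dup <- GeneMatrix(matrix(c(1, 2), 2, dimnames =
                             list(c("TCGA-3C-AALK-01A-11D-A41Q-05",
                                    "TCGA-3C-AALK-01A-21D-A41Q-05"), "GDA")),
                    c("tumoral", "tumoral"), "dnaMeth")
  expect_error(combineMatrices(dup, exampleRnaMatrix()), "ambiguous")
})

test_that("suffix rendering can be switched to the abbreviated form", {
  cm <- combineMatrices(exampleMethMatrix(), exampleRnaMatrix(),
                        suffixes = c("_dMeth", "_rna"))
  expect_true(all(c("GDA_dMeth", "GDA_rna") %in% featureIDs(cm)))
})
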
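#' Combine methylation and expression matrices by full outer join
#'
#' Builds the combined multi-omics matrix: sample identifiers of both
#' single-experiment matrices are truncated to their 4-field barcode
#' prefix (dropping the experiment-describing fields), rows are the union
#' of truncated IDs, and the feature list is the concatenation of the
#' methylation features suffixed `"_dnaMeth"` and the expression features
#' suffixed `"_rnaSeq"` (so the combined width is exactly the sum of the
#' input widths, even when gene symbols overlap between experiments).
#' A sample present in only one experiment has every feature of the other
#' experiment missing (`NA`, rendered "?"); values present in an input are
#' carried over verbatim. The class label is taken from whichever input
#' provides the sample; conflicting labels across inputs are an error.
#'
#' @param meth a [GeneMatrix-class] with `experimentTag == "dnaMeth"`.
#' @param rna a [GeneMatrix-class] with `experimentTag == "rnaSeq"`.
#' @param suffixes length-2 character, the feature-name suffixes for the
#'   methylation and expression namespaces.
#' @param completeCases if `TRUE`, keep only samples present in both
#'   experiments (drops the rows that would carry a fully missing block).
#' @return A [GeneMatrix-class] with `experimentTag == "combined"`.
#' @examples
#' meth <- GeneMatrix(matrix(c(1.6, 2.3), 1,
#'                    dimnames = list("TCGA-A7-A4SD-01A-11D-A268-05",
#'                                    c("GDA", "SCN3A"))),
#'                    "tumoral", "dnaMeth")
#' rna <- GeneMatrix(matrix(c(0.0, 6.4), 1,
#'                   dimnames = list("TCGA-A7-A4SD-01A-11R-A266-07",
#'                                   c("GDA", "SCN3A"))),
#'                   "tumoral", "rnaSeq")
#' combineMatrices(meth, rna)
#' @export
combineMatrices <- function(meth, rna,
                            suffixes = c("_dnaMeth", "_rnaSeq"),
                            completeCases = FALSE) {
  stopifnot(is(meth, "GeneMatrix"), is(rna, "GeneMatrix"),
            length(suffixes) == 2L)
  if (experimentTag(meth) == "combined" || experimentTag(rna) == "combined") {
    stop("inputs must be single-experiment matrices", call. = FALSE)
  }

  truncIDs <- function(x) {
    ids <- sampleIDs(x)
    if (!length(ids)) return(character(0))
    tr <- truncateBarcode(ids)
    dup <- tr[duplicated(tr)]
    if (length(dup)) {
      stop("ambiguous input (", experimentTag(x), "): multiple aliquots map to ",
           "the same truncated sample ID: ", paste(unique(dup), collapse = ", "),
           call. = FALSE)
    }
    tr
  }
  idM <- truncIDs(meth)
  idR <- truncIDs(rna)

  labM <- stats::setNames(unname(classLabels(meth)), idM)
  labR <- stats::setNames(unname(classLabels(rna)), idR)
  shared <- intersect(idM, idR)
  conflict <- shared[!is.na(labM[shared]) & !is.na(labR[shared]) &
                       labM[shared] != labR[shared]]
  if (length(conflict)) {
    stop("conflicting class labels between experiments for sample(s): ",
         paste(conflict, collapse = ", "), call. = FALSE)
  }

  allIDs <- sort(union(idM, idR))
  if (completeCases) allIDs <- sort(shared)

  valsM <- matrixValues(meth)
  valsR <- matrixValues(rna)
  rownames(valsM) <- idM
  rownames(valsR) <- idR
  featM <- if (ncol(valsM)) paste0(colnames(valsM), suffixes[1L]) else character(0)
  featR <- if (ncol(valsR)) paste0(colnames(valsR), suffixes[2L]) else character(0)

  out <- matrix(NA_real_, nrow = length(allIDs),
                ncol = length(featM) + length(featR),
                dimnames = list(allIDs, c(featM, featR)))
  inM <- allIDs[allIDs %in% idM]
  inR <- allIDs[allIDs %in% idR]
  if (length(inM) && length(featM)) out[inM, featM] <- valsM[inM, , drop = FALSE]
  if (length(inR) && length(featR)) out[inR, featR] <- valsR[inR, , drop = FALSE]

  labels <- ifelse(allIDs %in% idM & !is.na(labM[allIDs]),
                   labM[allIDs], labR[allIDs])
  GeneMatrix(out, classLabels = unname(labels), experimentTag = "combined")
}
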
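#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.EXPERIMENT_TAGS <- c("dnaMeth", "rnaSeq", "combined")
.CLASS_LEVELS <- c("normal", "tumoral")

#' SampleBarcode: structured TCGA aliquot identifier
#'
#' A parsed TCGA aliquot barcode such as `TCGA-A7-A4SD-01A-11D-A268-05`.
#' The first four dash-separated fields identify the tissue sample
#' (project, tissue source site, participant, sample-type code + vial);
#' the remaining fields describe the performed experiment (portion/analyte,
#' plate, sequencing center) and are empty strings when absent.
#'
#' The two leading digits of `sampleVial` are the TCGA sample-type code:
#' 01-09 are tumor tissues, 10-19 normal tissues, 20-29 controls.
#'
#' @slot project character, e.g. `"TCGA"`.
#' @slot tss character tissue source site code.
#' @slot participant character participant code.
#' @slot sampleVial character, 2-digit sample-type code plus vial letter.
#' @slot portionAnalyte,plate,center character, possibly `""`.
#' @seealso [parseBarcode()], [truncateBarcode()], [classFromBarcode()]
#' @export
setClass("SampleBarcode",
  representation(
    project = "character",
    tss = "character",
    participant = "character",
    sampleVial = "character",
    portionAnalyte = "character",
    plate = "character",
    center = "character"
  )
)

setValidity("SampleBarcode", function(object) {
  msgs <- character()
  for (s in c("project", "tss", "participant", "sampleVial",
              "portionAnalyte", "plate", "center")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v)) msgs <- c(msgs, paste0("slot '", s, "' must be a single non-NA string"))
  }
  if (length(msgs)) return(msgs)
  for (s in c("project", "tss", "participant", "sampleVial")) {
    if (!nzchar(slot(object, s))) msgs <- c(msgs, paste0("mandatory field '", s, "' is empty"))
  }
  code <- suppressWarnings(as.integer(substr(object@sampleVial, 1L, 2L)))
  if (is.na(code) || !grepl("^[0-9]{2}", object@sampleVial)) {
    msgs <- c(msgs, "sample-type code (first two characters of the sample/vial field) must be numeric")
  } else if (code < 1L || code > 29L) {
    msgs <- c(msgs, sprintf("sample-type code %02d outside the supported range [01, 29]", code))
  }
  if (length(msgs)) msgs else TRUE
})

#' GeneMatrix: samples x genes data matrix with class labels
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding one
#' assay named `"values"` with genes (features) in rows and samples in
#' columns, a mandatory `Class` column in `colData` with levels
#' `normal`/`tumoral` (NA allowed only transiently), and an
#' `experimentTag` metadata entry, one of `"dnaMeth"`, `"rnaSeq"`,
#' `"combined"`. Missing measurements (the "?" of the CSV rendering) are
#' `NA` in the assay.
#'
#' @seealso [GeneMatrix()], [buildGeneMatrix()], [combineMatrices()],
#'   [readGeneMatrix()], [writeGeneMatrix()]
#' @export
setClass("GeneMatrix", contains = "SummarizedExperiment")

setValidity("GeneMatrix", function(object) {
  msgs <- character()
  if (length(SummarizedExperiment::assays(object)) < 1L ||
      !identical(assayNames(object)[1L], "values")) {
    msgs <- c(msgs, "first assay must be named 'values'")
  }
  if (!"Class" %in% colnames(colData(object))) {
    msgs <- c(msgs, "colData must contain a 'Class' column")
  } else {
    cl <- as.character(colData(object)$Class)
    bad <- cl[!is.na(cl) & !cl %in% .CLASS_LEVELS]
    if (length(bad)) msgs <- c(msgs, paste0("unknown class label(s): ", paste(unique(bad), collapse = ", ")))
  }
  tag <- metadata(object)$experimentTag
  if (is.null(tag) || !is.character(tag) || length(tag) != 1L || !tag %in% .EXPERIMENT_TAGS) {
    msgs <- c(msgs, "metadata$experimentTag must be one of 'dnaMeth', 'rnaSeq', 'combined'")
  }
  if (ncol(object) && (is.null(colnames(object)) || anyDuplicated(colnames(object)))) {
    msgs <- c(msgs, "sample IDs (colnames) must be present and unique")
  }
  if (nrow(object) && (is.null(rownames(object)) || anyDuplicated(rownames(object)))) {
    msgs <- c(msgs, "feature names (rownames) must be present and unique")
  }
  if (length(msgs)) msgs else TRUE
})

#' Rule: one conjunctive threshold rule
#'
#' An if-then rule of the form
#' `(F <= t) and (G >= u) -> class = c`: a conjunction of numeric threshold
#' conditions on features plus a target class. The `conditions` slot is a
#' data.frame with columns `feature` (character), `op` (`"<="` or `">="`)
#' and `threshold` (numeric); zero rows encode the empty conjunction,
#' which covers every sample.
#'
#' @slot conditions data.frame of conditions (columns feature/op/threshold).
#' @slot targetClass character class label assigned when the rule covers.
#' @export
setClass("Rule",
  representation(conditions = "data.frame", targetClass = "character")
)

setValidity("Rule", function(object) {
  msgs <- character()
  cond <- object@conditions
  if (!all(c("feature", "op", "threshold") %in% colnames(cond))) {
    msgs <- c(msgs, "conditions must have columns feature, op, threshold")
  } else {
    if (nrow(cond)) {
      if (!all(cond$op %in% c("<=", ">="))) msgs <- c(msgs, "op must be '<=' or '>='")
      if (!is.numeric(cond$threshold)) msgs <- c(msgs, "threshold must be numeric")
    }
  }
  if (length(object@targetClass) != 1L || is.na(object@targetClass)) {
    msgs <- c(msgs, "targetClass must be a single class label")
  }
  if (length(msgs)) msgs else TRUE
})

#' RuleModel: ordered rule list with a default class
#'
#' A rule-based classification model: an ordered list of [Rule-class]
#' objects evaluated first-match, plus a default class for samples covered
#' by no rule, and the macro F-measure the model attains on its training
#' data.
#'
#' @slot rules list of [Rule-class] objects (possibly empty).
#' @slot defaultClass character default class label.
#' @slot trainFMeasure numeric in \[0, 1\].
#' @seealso [learnRuleset()], [predict,RuleModel-method]
#' @export
setClass("RuleModel",
  representation(rules = "list", defaultClass = "character",
                 trainFMeasure = "numeric")
)

setValidity("RuleModel", function(object) {
  msgs <- character()
  if (!all(vapply(object@rules, is, logical(1L), class2 = "Rule"))) {
    msgs <- c(msgs, "rules must be a list of Rule objects")
  } else if (any(vapply(object@rules, function(r) nrow(r@conditions) == 0L, logical(1L)))) {
    msgs <- c(msgs, "non-default rules must have at least one condition")
  }
  if (length(object@defaultClass) != 1L || is.na(object@defaultClass)) {
    msgs <- c(msgs, "defaultClass must be a single class label")
  }
  f <- object@trainFMeasure
  if (length(f) != 1L || is.na(f) || f < 0 || f > 1) {
    msgs <- c(msgs, "trainFMeasure must be a single value in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' CamurConfig: configuration of the iterative multi-model extraction
#'
#' Defaults mirror the study settings for the iterative rule-model
#' extraction: loose execution mode, minimum cross-validated F-measure
#' 0.8 for archiving a model, at most 100 iterations, a (generous) wall
#' time cap, and 10-fold internal cross-validation.
#'
#' @slot mode `"standard"` or `"loose"`.
#' @slot fThreshold numeric in (0, 1], minimum CV F-measure to archive.
#' @slot maxIterations positive integer iteration cap.
#' @slot maxTime numeric wall-time cap in seconds.
#' @slot seed integer master seed.
#' @slot cvFolds integer folds of the per-iteration cross-validation.
#' @slot ripperParams list of parameters forwarded to [learnRuleset()].
#' @seealso [camurConfig()], [runCamur()]
#' @export
setClass("CamurConfig",
  representation(mode = "character", fThreshold = "numeric",
                 maxIterations = "integer", maxTime = "numeric",
                 seed = "integer", cvFolds = "integer",
                 ripperParams = "list")
)

setValidity("CamurConfig", function(object) {
  msgs <- character()
  if (!object@mode %in% c("standard", "loose")) msgs <- c(msgs, "mode must be 'standard' or 'loose'")
  if (!(object@fThreshold > 0 && object@fThreshold <= 1)) {
    msgs <- c(msgs, "fThreshold must lie in (0, 1]")
  }
  if (object@maxIterations < 1L) msgs <- c(msgs, "maxIterations must be positive")
  if (object@maxTime <= 0) msgs <- c(msgs, "maxTime must be positive")
  if (object@cvFolds < 2L) msgs <- c(msgs, "cvFolds must be at least 2")
  if (length(msgs)) msgs else TRUE
})

#' CamurRun: archive of models produced by the iterative extraction
#'
#' @slot models list; each element a list with components `model`
#'   ([RuleModel-class]), `eliminated` (character vector of features removed
#'   before training), and `cvFMeasure` (numeric).
#' @slot iterationsExecuted integer, number of training iterations run.
#' @slot stopReason one of `"below_threshold"`, `"max_iterations"`,
#'   `"time_limit"`, `"exhausted"`.
#' @slot config the [CamurConfig-class] used.
#' @seealso [runCamur()], [analyzeRun()]
#' @export
setClass("CamurRun",
  representation(models = "list", iterationsExecuted = "integer",
                 stopReason = "character", config = "CamurConfig")
)

setValidity("CamurRun", function(object) {
  msgs <- character()
  if (!object@stopReason %in% c("below_threshold", "max_iterations", "time_limit", "exhausted")) {
    msgs <- c(msgs, "unknown stopReason")
  }
  ok <- vapply(object@models, function(m) {
    is.list(m) && all(c("model", "eliminated", "cvFMeasure") %in% names(m)) &&
      is(m$model, "RuleModel")
  }, logical(1L))
  if (!all(ok)) msgs <- c(msgs, "each archived model needs components model/eliminated/cvFMeasure")
  if (length(msgs)) msgs else TRUE
})

#' CohortSpec: parameters of the synthetic TCGA-like cohort generator
#'
#' Describes a two-class cohort with per-sample site-level methylation
#' files and gene-level expression files. A subset of genes is "planted":
#' their measurements carry a class-dependent shift, so downstream
#' classifiers have a known ground truth to recover.
#'
#' @slot nTumoral,nNormal integer sample counts per class.
#' @slot nGenes integer size of the gene universe.
#' @slot sitesPerGene integer range (length-2) of CpG sites per gene.
#' @slot plantedMethGenes,plantedRnaGenes character vectors of planted genes.
#' @slot effectSize numeric shift between classes in units of the
#'   background standard deviation (beta scale for methylation,
#'   log-expression scale for RNA).
#' @slot overlap named numeric fractions `both`, `onlyMeth`, `onlyRna`
#'   summing to 1: availability of the two experiments per sample.
#' @slot seed integer.
#' @seealso [cohortSpec()], [simulateCohort()]
#' @export
setClass("CohortSpec",
  representation(nTumoral = "integer", nNormal = "integer", nGenes = "integer",
                 sitesPerGene = "integer", plantedMethGenes = "character",
                 plantedRnaGenes = "character", effectSize = "numeric",
                 overlap = "numeric", seed = "integer")
)

setValidity("CohortSpec", function(object) {
  msgs <- character()
  if (object@nTumoral < 0L || object@nNormal < 0L) msgs <- c(msgs, "sample counts must be nonnegative")
  if (object@nGenes < 1L) msgs <- c(msgs, "nGenes must be positive")
  if (length(object@sitesPerGene) != 2L || any(object@sitesPerGene < 1L) ||
      object@sitesPerGene[1L] > object@sitesPerGene[2L]) {
    msgs <- c(msgs, "sitesPerGene must be an increasing pair of positive integers")
  }
  if (object@effectSize < 0) msgs <- c(msgs, "effectSize must be nonnegative")
  if (!identical(sort(names(object@overlap)), sort(c("both", "onlyMeth", "onlyRna")))) {
    msgs <- c(msgs, "overlap must have entries both/onlyMeth/onlyRna")
  } else if (abs(sum(object@overlap) - 1) > 1e-8 || any(object@overlap < 0)) {
    msgs <- c(msgs, "overlap fractions must be nonnegative and sum to 1")
  }
  if (length(msgs)) msgs else TRUE
})
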
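#' @rdname GeneMatrix-accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname GeneMatrix-accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname GeneMatrix-accessors
#' @export
setGeneric("experimentTag", function(x) standardGeneric("experimentTag"))

#' @rdname GeneMatrix-accessors
#' @export
setGeneric("matrixValues", function(x) standardGeneric("matrixValues"))

#' @rdname GeneMatrix-accessors
#' @export
setGeneric("featureIDs", function(x) standardGeneric("featureIDs"))

#' @rdname truncateBarcode
#' @export
setGeneric("truncateBarcode", function(x) standardGeneric("truncateBarcode"))

#' @rdname formatBarcode
#' @export
setGeneric("formatBarcode", function(x) standardGeneric("formatBarcode"))

#' @rdname classFromBarcode
#' @export
setGeneric("classFromBarcode", function(x) standardGeneric("classFromBarcode"))

#' @rdname covers
#' @export
setGeneric("covers", function(rule, sample) standardGeneric("covers"))

#' @rdname runCamur
#' @export
setGeneric("runCamur", function(x, config, ...) standardGeneric("runCamur"))

#' @rdname analyzeRun
#' @export
setGeneric("analyzeRun", function(run) standardGeneric("analyzeRun"))

#' @rdname genesFromModel
#' @export
setGeneric("genesFromModel", function(x, ...) standardGeneric("genesFromModel"))

#' @rdname simulateCohort
#' @export
setGeneric("simulateCohort", function(spec, outDir, ...) standardGeneric("simulateCohort"))
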
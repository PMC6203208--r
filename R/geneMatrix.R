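#' Construct a GeneMatrix
#'
#' @param values numeric matrix, samples in rows and gene features in
#'   columns (the orientation of the CSV rendering); it is stored
#'   transposed, features-by-samples, in the underlying
#'   `SummarizedExperiment`.
#' @param classLabels character vector of `"normal"`/`"tumoral"` labels,
#'   one per sample.
#' @param experimentTag `"dnaMeth"`, `"rnaSeq"` or `"combined"`.
#' @return A [GeneMatrix-class] object.
#' @examples
#' m <- GeneMatrix(matrix(1:4, 2, dimnames = list(c("S1", "S2"), c("A", "B"))),
#'                 classLabels = c("normal", "tumoral"),
#'                 experimentTag = "rnaSeq")
#' sampleIDs(m)
#' @export
GeneMatrix <- function(values, classLabels, experimentTag) {
  stopifnot(is.matrix(values))
  storage.mode(values) <- "double"
  .assertClassLabels(classLabels)
  if (length(classLabels) != nrow(values)) {
    stop("need one class label per sample (row)", call. = FALSE)
  }
  se <- SummarizedExperiment(
    assays = list(values = t(values)),
    colData = DataFrame(Class = as.character(classLabels),
                        row.names = rownames(values)),
    metadata = list(experimentTag = experimentTag)
  )
  new("GeneMatrix", se)
}

#' Accessors for GeneMatrix objects
#'
#' `sampleIDs` returns the sample identifiers, `featureIDs` the gene
#' feature names, `classLabels` the per-sample class labels, and
#' `matrixValues` the samples-by-features numeric matrix (missing entries
#' as `NA`). `experimentTag` returns which experiment the matrix holds.
#'
#' @param x a [GeneMatrix-class].
#' @name GeneMatrix-accessors
#' @aliases sampleIDs classLabels experimentTag matrixValues featureIDs
NULL

#' @rdname GeneMatrix-accessors
#' @export
setMethod("sampleIDs", "GeneMatrix", function(x) colnames(x))

#' @rdname GeneMatrix-accessors
#' @export
setMethod("featureIDs", "GeneMatrix", function(x) rownames(x))

#' @rdname GeneMatrix-accessors
#' @export
setMethod("classLabels", "GeneMatrix", function(x) {
  stats::setNames(as.character(colData(x)$Class), colnames(x))
})

#' @rdname GeneMatrix-accessors
#' @export
setMethod("experimentTag", "GeneMatrix", function(x) metadata(x)$experimentTag)

#' @rdname GeneMatrix-accessors
#' @export
setMethod("matrixValues", "GeneMatrix", function(x) t(assay(x, "values")))

setMethod("show", "GeneMatrix", function(object) {
  cl <- classLabels(object)
  cat(sprintf("GeneMatrix [%s]: %d samples x %d features\n",
              experimentTag(object), ncol(object), nrow(object)))
  cat(sprintf("  classes: %d tumoral, %d normal; missing entries: %d\n",
              sum(cl == "tumoral", na.rm = TRUE),
              sum(cl == "normal", na.rm = TRUE),
              sum(is.na(assay(object, "values")))))
})

#' Aggregate site-level methylation to the gene methylation quantity
#'
#' The gene methylation quantity of gene *j* in one sample is the sum of
#' the beta values of all CpG sites annotated to that gene,
#' \eqn{b_j = \sum_h a_{jh}}. Sites with an empty gene symbol (methylation
#' outside annotated genes) are excluded, as are sites with a missing beta
#' value, so missingness never propagates into the sum. Composite gene
#' annotations such as `"A;B"` contribute the site's beta to every listed
#' gene.
#'
#' @param records data.frame of site records as returned by
#'   [readMethylationFile()] (columns `gene` and `beta` are used).
#' @return named numeric vector, gene symbol to methylation quantity,
#'   sorted by gene symbol; empty for empty input.
#' @examples
#' recs <- data.frame(gene = c("GDA", "GDA", "GDA"), beta = c(0.4, 0.7, 0.5))
#' aggregateMethylation(recs) # GDA = 1.6
#' @export
aggregateMethylation <- function(records) {
  stopifnot(is.data.frame(records), all(c("gene", "beta") %in% names(records)))
  keep <- !is.na(records$beta) & nzchar(records$gene)
  gene <- records$gene[keep]
  beta <- records$beta[keep]
  if (!length(gene)) return(stats::setNames(numeric(0), character(0)))
  # split composite annotations ("A;B") onto each listed gene
  if (any(grepl(";", gene, fixed = TRUE))) {
    parts <- strsplit(gene, ";", fixed = TRUE)
    n <- lengths(parts)
    gene <- unlist(parts, use.names = FALSE)
    beta <- rep(beta, n)
    keep2 <- nzchar(gene)
    gene <- gene[keep2]
    beta <- beta[keep2]
  }
  agg <- vapply(split(beta, gene), sum, numeric(1L))
  agg[order(names(agg))]
}

#' Assemble a samples x genes matrix from per-sample gene values
#'
#' The feature set is the sorted union of genes over all samples; a gene
#' unobserved in a sample's file is missing (`NA`, rendered "?") by
#' default, since absence of measurement is not zero methylation or
#' expression. Rows are ordered by sample identifier.
#'
#' @param perSample named list: sample ID to named numeric vector of
#'   gene values.
#' @param labels named character vector of class labels covering every
#'   sample in `perSample`.
#' @param experimentTag `"dnaMeth"` or `"rnaSeq"`.
#' @param fill fill value for unobserved genes: `NA` (default) or `0`.
#' @return A [GeneMatrix-class].
#' @export
buildGeneMatrix <- function(perSample, labels, experimentTag,
                            fill = NA_real_) {
  stopifnot(is.list(perSample))
  ids <- names(perSample)
  if (length(perSample) && (is.null(ids) || any(!nzchar(ids)))) {
    stop("perSample must be a named list of sample vectors", call. = FALSE)
  }
  missingLab <- setdiff(ids, names(labels))
  if (length(missingLab)) {
    stop("no class label for sample(s): ", paste(missingLab, collapse = ", "),
         call. = FALSE)
  }
  ids <- sort(ids)
  genes <- sort(unique(unlist(lapply(perSample, names), use.names = FALSE)))
  values <- matrix(as.numeric(fill), nrow = length(ids), ncol = length(genes),
                   dimnames = list(ids, genes))
  for (s in ids) {
    v <- perSample[[s]]
    if (length(v)) values[s, names(v)] <- as.numeric(v)
  }
  GeneMatrix(values, classLabels = as.character(labels[ids]),
             experimentTag = experimentTag)
}

#' Write / read a GeneMatrix as CSV
#'
#' The CSV layout has one row per sample: first column `Sample_ID`, then
#' one column per gene feature, last column `Class`. Missing values are
#' rendered as `"?"`. `readGeneMatrix` inverts `writeGeneMatrix`
#' (`read(write(x))` equals `x`).
#'
#' @param x a [GeneMatrix-class].
#' @param path CSV file path.
#' @param experimentTag tag to attach on read (`"dnaMeth"`, `"rnaSeq"` or
#'   `"combined"`).
#' @return `writeGeneMatrix` returns `path` invisibly; `readGeneMatrix`
#'   returns a [GeneMatrix-class].
#' @export
writeGeneMatrix <- function(x, path) {
  stopifnot(is(x, "GeneMatrix"))
  vals <- matrixValues(x)
  header <- c("Sample_ID", colnames(vals), "Class")
  if (anyDuplicated(header)) {
    stop("duplicate header names after adding Sample_ID/Class", call. = FALSE)
  }
  body <- matrix(renderValues(vals), nrow = nrow(vals))
  dt <- data.table::data.table(Sample_ID = rownames(vals))
  if (ncol(body)) {
    dt <- cbind(dt, data.table::as.data.table(body))
  }
  dt[["Class"]] <- renderValues(classLabels(x))
  data.table::setnames(dt, header)
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' @rdname writeGeneMatrix
#' @export
readGeneMatrix <- function(path, experimentTag) {
  caught <- character(0)
  dt <- withCallingHandlers(
    tryCatch(
      data.table::fread(path, sep = ",", header = TRUE,
                        colClasses = "character", fill = FALSE,
                        data.table = TRUE, showProgress = FALSE),
      error = function(e) stop("format error reading matrix '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    ),
    warning = function(w) {
      caught <<- c(caught, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (length(caught)) {
    stop("format error reading matrix '", path, "': ", caught[1L],
         call. = FALSE)
  }
  hdr <- colnames(dt)
  if (length(hdr) < 2L || hdr[1L] != "Sample_ID" || hdr[length(hdr)] != "Class") {
    stop("matrix CSV must start with Sample_ID and end with Class", call. = FALSE)
  }
  if (anyDuplicated(hdr)) {
    stop("duplicate header names in '", path, "'", call. = FALSE)
  }
  genes <- hdr[-c(1L, length(hdr))]
  ids <- dt[["Sample_ID"]]
  vals <- matrix(NA_real_, nrow = length(ids), ncol = length(genes),
                 dimnames = list(ids, genes))
  for (j in seq_along(genes)) {
    vals[, j] <- .parseNumeric(dt[[genes[j]]], c("?", "NA", ""), path, "matrix")
  }
  cls <- dt[["Class"]]
  cls[cls == "?"] <- NA_character_
  GeneMatrix(vals, classLabels = cls, experimentTag = experimentTag)
}

#' Subset a GeneMatrix to a feature set
#'
#' @param x a [GeneMatrix-class].
#' @param features character vector of feature names to keep.
#' @return A [GeneMatrix-class] with the selected features.
#' @export
selectFeatures <- function(x, features) {
  stopifnot(is(x, "GeneMatrix"), all(features %in% featureIDs(x)))
  out <- x[features, ]
  metadata(out)$experimentTag <- experimentTag(x)
  out
}
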
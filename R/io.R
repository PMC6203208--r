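#' File dialect for per-sample experiment files
#'
#' Per-sample methylation files are tab-separated, BED-like, one CpG site
#' per line; per-sample expression files carry one gene per line. The
#' exact column layout differs between export tools, so it is declared in
#' a dialect object: 1-based column indices for each field, the separator,
#' and the tokens that denote a missing value.
#'
#' @param methColumns named integer vector with entries `chrom`, `start`,
#'   `end`, `strand`, `gene`, `beta`.
#' @param exprColumns named integer vector with entries `gene`, `value`.
#' @param sep field separator.
#' @param missingTokens character values read as missing.
#' @return A list of class `"fileDialect"`.
#' @examples
#' d <- fileDialect()
#' d$methColumns
#' @export
fileDialect <- function(methColumns = c(chrom = 1L, start = 2L, end = 3L,
                                        strand = 4L, gene = 5L, beta = 6L),
                        exprColumns = c(gene = 1L, value = 2L),
                        sep = "\t",
                        missingTokens = c("NA", ".", "?", "")) {
  stopifnot(all(c("chrom", "start", "end", "strand", "gene", "beta") %in%
                  names(methColumns)),
            all(c("gene", "value") %in% names(exprColumns)))
  structure(list(methColumns = methColumns, exprColumns = exprColumns,
                 sep = sep, missingTokens = missingTokens),
            class = "fileDialect")
}

#' Read a file dialect from a YAML or JSON config block
#'
#' The block may contain `meth_columns`, `expr_columns` (named 1-based
#' indices), `separator` and `missing_tokens`; absent entries fall back to
#' the defaults of [fileDialect()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `"fileDialect"` list.
#' @export
readDialect <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  d <- fileDialect()
  if (!is.null(cfg$meth_columns)) {
    mc <- unlist(cfg$meth_columns)
    d$methColumns[names(mc)] <- as.integer(mc)
  }
  if (!is.null(cfg$expr_columns)) {
    ec <- unlist(cfg$expr_columns)
    d$exprColumns[names(ec)] <- as.integer(ec)
  }
  if (!is.null(cfg$separator)) d$sep <- cfg$separator
  if (!is.null(cfg$missing_tokens)) d$missingTokens <- as.character(cfg$missing_tokens)
  d
}

.readLinesTable <- function(path, sep, ncolNeeded, what) {
  if (!file.exists(path)) stop("cannot read ", what, " file '", path, "'", call. = FALSE)
  if (file.size(path) == 0L) return(data.table::data.table())
  dt <- tryCatch(
    data.table::fread(path, sep = sep, header = FALSE, colClasses = "character",
                      fill = FALSE, data.table = TRUE, showProgress = FALSE,
                      blank.lines.skip = TRUE),
    error = function(e) stop("I/O error reading ", what, " file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(dt) == 0L) return(dt)
  if (ncol(dt) < ncolNeeded) {
    stop("wrong column count in ", what, " file '", path, "': need at least ",
         ncolNeeded, ", found ", ncol(dt), " (line 1)", call. = FALSE)
  }
  dt
}

.parseNumeric <- function(x, missingTokens, path, what) {
  miss <- x %in% missingTokens | is.na(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!miss & is.na(out))
  if (length(bad)) {
    stop("non-numeric ", what, " value '", x[bad[1L]], "' in '", path,
         "' at line ", bad[1L], call. = FALSE)
  }
  out[miss] <- NA_real_
  out
}

#' Read a per-sample methylation file
#'
#' Reads one tab-separated BED-like file of CpG-site measurements into a
#' data.frame with columns `chrom`, `start`, `end`, `strand`, `gene`,
#' `beta`. Sites with a missing beta (tokens in `dialect$missingTokens`)
#' are retained with `beta = NA`; they are skipped later by
#' [aggregateMethylation()].
#'
#' @param path file path.
#' @param dialect a [fileDialect()].
#' @return data.frame of site records (zero rows for an empty file).
#' @export
readMethylationFile <- function(path, dialect = fileDialect()) {
  cols <- dialect$methColumns
  dt <- .readLinesTable(path, dialect$sep, max(cols), "methylation")
  if (nrow(dt) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), gene = character(),
                      beta = numeric(), stringsAsFactors = FALSE))
  }
  start <- as.integer(.parseNumeric(dt[[cols[["start"]]]], character(), path, "start"))
  end <- as.integer(.parseNumeric(dt[[cols[["end"]]]], character(), path, "end"))
  bad <- which(!(start >= 0L & start < end))
  if (length(bad)) {
    stop("invalid interval (need 0 <= start < end) in '", path, "' at line ",
         bad[1L], call. = FALSE)
  }
  beta <- .parseNumeric(dt[[cols[["beta"]]]], dialect$missingTokens, path, "beta")
  out <- which(!is.na(beta) & (beta < 0 | beta > 1))
  if (length(out)) {
    stop("beta value ", beta[out[1L]], " outside [0, 1] in '", path,
         "' at line ", out[1L], call. = FALSE)
  }
  gene <- dt[[cols[["gene"]]]]
  gene[gene %in% dialect$missingTokens] <- ""
  data.frame(chrom = dt[[cols[["chrom"]]]], start = start, end = end,
             strand = dt[[cols[["strand"]]]], gene = gene, beta = beta,
             stringsAsFactors = FALSE)
}

#' Read a per-sample expression file
#'
#' Reads one tab-separated file of normalized RSEM expression values into
#' a data.frame with columns `gene`, `value`. Gene symbols must be unique
#' within a file; values must be nonnegative.
#'
#' @inheritParams readMethylationFile
#' @return data.frame of expression records.
#' @export
readExpressionFile <- function(path, dialect = fileDialect()) {
  cols <- dialect$exprColumns
  dt <- .readLinesTable(path, dialect$sep, max(cols), "expression")
  if (nrow(dt) == 0L) {
    return(data.frame(gene = character(), value = numeric(),
                      stringsAsFactors = FALSE))
  }
  gene <- dt[[cols[["gene"]]]]
  dup <- gene[duplicated(gene)]
  if (length(dup)) {
    stop("duplicate gene line(s) in expression file '", path, "': ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  value <- .parseNumeric(dt[[cols[["value"]]]], dialect$missingTokens, path, "expression")
  neg <- which(!is.na(value) & value < 0)
  if (length(neg)) {
    stop("negative expression value in '", path, "' at line ", neg[1L],
         call. = FALSE)
  }
  data.frame(gene = gene, value = value, stringsAsFactors = FALSE)
}
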
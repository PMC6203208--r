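#' Parse a TCGA aliquot barcode
#'
#' Splits a dash-separated TCGA barcode into its positional fields. At
#' least the four sample-identifying fields (project, tissue source site,
#' participant, sample-type code + vial) must be present; the
#' experiment-describing fields (portion/analyte, plate, center) are
#' optional and stored as empty strings when absent.
#'
#' @param aliquot character(1), e.g. `"TCGA-A7-A4SD-01A-11D-A268-05"`.
#' @return A [SampleBarcode-class] object.
#' @examples
#' b <- parseBarcode("TCGA-A7-A4SD-01A-11D-A268-05")
#' truncateBarcode(b)
#' classFromBarcode(b)
#' @export
parseBarcode <- function(aliquot) {
  if (!is.character(aliquot) || length(aliquot) != 1L || is.na(aliquot)) {
    stop("barcode must be a single string", call. = FALSE)
  }
  parts <- strsplit(aliquot, "-", fixed = TRUE)[[1L]]
  if (length(parts) < 4L) {
    stop("malformed barcode '", aliquot, "': expected at least 4 dash-separated ",
         "fields (project-tss-participant-sample), got ", length(parts),
         call. = FALSE)
  }
  if (length(parts) > 7L) {
    stop("malformed barcode '", aliquot, "': more than 7 fields", call. = FALSE)
  }
  if (any(!nzchar(parts[1:4]))) {
    stop("malformed barcode '", aliquot, "': empty mandatory field", call. = FALSE)
  }
  if (!grepl("^[0-9]{2}", parts[4L])) {
    stop("malformed barcode '", aliquot, "': sample field '", parts[4L],
         "' does not start with a 2-digit sample-type code", call. = FALSE)
  }
  parts <- c(parts, rep("", 7L - length(parts)))
  new("SampleBarcode",
      project = parts[1L], tss = parts[2L], participant = parts[3L],
      sampleVial = parts[4L], portionAnalyte = parts[5L],
      plate = parts[6L], center = parts[7L])
}

#' Dash-joined string form of a barcode
#'
#' Inverse of [parseBarcode()]: joins the populated fields with dashes,
#' dropping trailing empty (absent) fields.
#'
#' @param x a [SampleBarcode-class].
#' @return character(1).
#' @rdname formatBarcode
#' @export
setMethod("formatBarcode", "SampleBarcode", function(x) {
  parts <- c(x@project, x@tss, x@participant, x@sampleVial,
             x@portionAnalyte, x@plate, x@center)
  last <- max(which(nzchar(parts)))
  paste(parts[seq_len(last)], collapse = "-")
})

#' Truncate a barcode to its sample-identifying prefix
#'
#' Drops the experiment-specific fields (portion/analyte, plate, center),
#' keeping the first four dash-joined fields. Tissue samples of the same
#' participant with different sample-type codes (e.g. tumor `01A` and
#' normal `11A`) remain distinct. Idempotent: a 4-field barcode maps to
#' itself.
#'
#' @param x a [SampleBarcode-class] or a character vector of barcode
#'   strings.
#' @return character of truncated (4-field) barcodes.
#' @rdname truncateBarcode
#' @export
setMethod("truncateBarcode", "SampleBarcode", function(x) {
  paste(x@project, x@tss, x@participant, x@sampleVial, sep = "-")
})

#' @rdname truncateBarcode
#' @export
setMethod("truncateBarcode", "character", function(x) {
  vapply(x, function(s) truncateBarcode(parseBarcode(s)), character(1L),
         USE.NAMES = FALSE)
})

#' Sample-type code of a barcode
#'
#' @param x a [SampleBarcode-class].
#' @return integer sample-type code (the two leading digits of the
#'   sample/vial field).
#' @export
sampleTypeCode <- function(x) {
  stopifnot(is(x, "SampleBarcode"))
  as.integer(substr(x@sampleVial, 1L, 2L))
}

#' Class label encoded by a barcode's sample-type code
#'
#' TCGA sample-type codes 01-09 denote tumor tissues and 10-19 normal
#' tissues; these map to the class labels `"tumoral"` and `"normal"`.
#' Control codes (20-29) are not supported for classification.
#'
#' @param x a [SampleBarcode-class] or character vector of barcode strings.
#' @return `"tumoral"` or `"normal"`.
#' @rdname classFromBarcode
#' @export
setMethod("classFromBarcode", "SampleBarcode", function(x) {
  code <- sampleTypeCode(x)
  if (code >= 1L && code <= 9L) return("tumoral")
  if (code >= 10L && code <= 19L) return("normal")
  stop("unsupported sample-type code ", sprintf("%02d", code),
       " (control samples cannot be assigned a tumoral/normal class)",
       call. = FALSE)
})

#' @rdname classFromBarcode
#' @export
setMethod("classFromBarcode", "character", function(x) {
  vapply(x, function(s) classFromBarcode(parseBarcode(s)), character(1L),
         USE.NAMES = FALSE)
})

setMethod("show", "SampleBarcode", function(object) {
  cat("SampleBarcode:", formatBarcode(object), "\n")
  cat("  sample-type code:", sprintf("%02d", sampleTypeCode(object)), "\n")
})
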
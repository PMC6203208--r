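#' Gene/experiment pairs used by a model or feature list
#'
#' Strips the experiment suffix (`"_dnaMeth"` / `"_rnaSeq"`) from feature
#' names and records which experiment each gene came from. Features
#' without a recognized suffix belong to a single-experiment matrix and
#' need `experiment` to be supplied; in a combined-matrix context an
#' unsuffixed feature is an error.
#'
#' @param x a [RuleModel-class], a [CamurRun-class], or a character
#'   vector of feature names.
#' @param experiment experiment tag (`"dnaMeth"` or `"rnaSeq"`) assumed
#'   for unsuffixed features; `NULL` (default) makes unsuffixed features
#'   an error.
#' @param suffixes named character vector mapping suffix to experiment.
#' @return data.frame with columns `gene` and `experiment`, duplicates
#'   collapsed, sorted.
#' @examples
#' genesFromModel(c("UMOD_rnaSeq", "VMP1_dnaMeth"))
#' @rdname genesFromModel
#' @export
setMethod("genesFromModel", "character", function(x, experiment = NULL,
                                                  suffixes = c("_dnaMeth" = "dnaMeth",
                                                               "_rnaSeq" = "rnaSeq")) {
  if (!length(x)) {
    return(data.frame(gene = character(), experiment = character(),
                      stringsAsFactors = FALSE))
  }
  gene <- character(length(x))
  expt <- character(length(x))
  for (i in seq_along(x)) {
    hit <- NA_integer_
    for (k in seq_along(suffixes)) {
      sfx <- names(suffixes)[k]
      if (endsWith(x[i], sfx) && nchar(x[i]) > nchar(sfx)) {
        hit <- k
        break
      }
    }
    if (!is.na(hit)) {
      gene[i] <- substr(x[i], 1L, nchar(x[i]) - nchar(names(suffixes)[hit]))
      expt[i] <- suffixes[[hit]]
    } else if (!is.null(experiment)) {
      gene[i] <- x[i]
      expt[i] <- experiment
    } else {
      stop("feature '", x[i], "' carries no recognized experiment suffix",
           call. = FALSE)
    }
  }
  out <- unique(data.frame(gene = gene, experiment = expt,
                           stringsAsFactors = FALSE))
  out[order(out$gene, out$experiment), , drop = FALSE]
})

#' @rdname genesFromModel
#' @export
setMethod("genesFromModel", "RuleModel", function(x, experiment = NULL, ...) {
  genesFromModel(ruleFeatures(x), experiment = experiment, ...)
})

#' @rdname genesFromModel
#' @export
setMethod("genesFromModel", "CamurRun", function(x, experiment = NULL, ...) {
  genesFromModel(runFeatures(x), experiment = experiment, ...)
})

#' Venn region counts for two or three named gene sets
#'
#' Computes the size of every inclusion-exclusion region of a 2- or
#' 3-set Venn diagram. Regions are named by the sets an element belongs
#' to, joined with `"&"` (e.g. `"A"`, `"A&B"`, `"A&B&C"`); each element
#' of the union is counted in exactly one region, so the counts sum to
#' the union size.
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return named integer vector of region counts.
#' @examples
#' vennRegionCounts(list(A = c("x", "y"), B = c("y", "z")))
#' @export
vennRegionCounts <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L ||
      is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be a named list of 2 or 3 gene sets", call. = FALSE)
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  nm <- names(sets)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L,
                                                   dimnames = list(NULL, nm))
  regionNames <- unlist(lapply(seq_along(nm), function(s) {
    utils::combn(nm, s, FUN = paste, collapse = "&")
  }))
  counts <- stats::setNames(integer(length(regionNames)), regionNames)
  if (length(universe)) {
    key <- apply(membership, 1L, function(row) paste(nm[row], collapse = "&"))
    tb <- table(key)
    counts[names(tb)] <- as.integer(tb)
  }
  counts
}

#' Write plain-text gene lists for each Venn region
#'
#' One file per region (one gene symbol per line), named
#' `<region>.txt` with `&` replaced by `_and_`.
#'
#' @param sets named list of 2 or 3 gene sets.
#' @param dir output directory (created if absent).
#' @return invisibly, the named character vector of file paths.
#' @export
writeVennRegions <- function(sets, dir) {
  counts <- vennRegionCounts(sets)   # validates input
  sets <- lapply(sets, function(s) unique(as.character(s)))
  nm <- names(sets)
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (region in names(counts)) {
    members <- strsplit(region, "&", fixed = TRUE)[[1L]]
    inAll <- universe
    for (s in nm) {
      inAll <- if (s %in% members) intersect(inAll, sets[[s]]) else setdiff(inAll, sets[[s]])
    }
    p <- file.path(dir, paste0(gsub("&", "_and_", region, fixed = TRUE), ".txt"))
    writeLines(sort(inAll), p)
    paths[region] <- p
  }
  invisible(paths)
}
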
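#' Specify a synthetic TCGA-like cohort
#'
#' Builds a [CohortSpec-class] describing a two-class cohort with planted
#' class-discriminative genes. Defaults describe a balanced cohort of 200
#' samples over a 500-gene universe with 10 planted genes (5 shifted in
#' methylation, 5 in expression), a strong effect (3 background standard
#' deviations), and 80% of samples measured in both experiments.
#'
#' @param nTumoral,nNormal samples per class (default 100 each).
#' @param nGenes gene universe size (default 500).
#' @param sitesPerGene inclusive range of CpG sites per gene (default
#'   `c(3, 8)`).
#' @param plantedMethGenes,plantedRnaGenes planted gene symbols; the
#'   defaults take the first 5 and next 5 genes of the universe.
#' @param effectSize class shift in background-SD units (beta scale for
#'   methylation, log-expression scale for RNA; default 3).
#' @param overlap named fractions `both` / `onlyMeth` / `onlyRna` of
#'   samples with the corresponding experiment availability (must sum to
#'   1; default 0.8/0.1/0.1).
#' @param seed integer (default 1).
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(nTumoral = 100L, nNormal = 100L, nGenes = 500L,
                       sitesPerGene = c(3L, 8L),
                       plantedMethGenes = NULL, plantedRnaGenes = NULL,
                       effectSize = 3,
                       overlap = c(both = 0.8, onlyMeth = 0.1, onlyRna = 0.1),
                       seed = 1L) {
  universe <- geneUniverse(nGenes)
  if (is.null(plantedMethGenes)) {
    plantedMethGenes <- universe[seq_len(min(5L, nGenes))]
  }
  if (is.null(plantedRnaGenes)) {
    plantedRnaGenes <- universe[seq_len(min(10L, nGenes))][-seq_len(min(5L, nGenes))]
  }
  bad <- setdiff(c(plantedMethGenes, plantedRnaGenes), universe)
  if (length(bad)) {
    stop("planted gene(s) outside the gene universe: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  new("CohortSpec", nTumoral = as.integer(nTumoral),
      nNormal = as.integer(nNormal), nGenes = as.integer(nGenes),
      sitesPerGene = as.integer(sitesPerGene),
      plantedMethGenes = as.character(plantedMethGenes),
      plantedRnaGenes = as.character(plantedRnaGenes),
      effectSize = as.numeric(effectSize),
      overlap = overlap[c("both", "onlyMeth", "onlyRna")],
      seed = as.integer(seed))
}

#' Gene universe of a synthetic cohort
#'
#' @param nGenes number of genes.
#' @return character vector `GENE0001`, `GENE0002`, ...
#' @export
geneUniverse <- function(nGenes) sprintf("GENE%04d", seq_len(nGenes))

# background distribution constants: Beta(2, 5) site-level betas
# (right-skewed, realistic for CpG methylation) and LogNormal(2, 1)
# expression
.BETA_SHAPE1 <- 2
.BETA_SHAPE2 <- 5
.BETA_SD <- sqrt(.BETA_SHAPE1 * .BETA_SHAPE2 /
                   ((.BETA_SHAPE1 + .BETA_SHAPE2)^2 *
                      (.BETA_SHAPE1 + .BETA_SHAPE2 + 1)))
.EXPR_MEANLOG <- 2
.EXPR_SDLOG <- 1

#' Generate a synthetic TCGA-like cohort on disk
#'
#' Emits per-sample site-level methylation files (tab-separated, BED-like:
#' chrom, start, end, strand, gene, beta), per-sample expression files
#' (gene, RSEM-like value), a `manifest.csv` mapping each file to its
#' aliquot barcode, and a `truth.json` ground-truth record.
#'
#' Background betas are Beta(2, 5); in tumoral samples every site of a
#' planted methylation gene is shifted by `effectSize` background SDs
#' (truncated to \[0, 1\]), so the gene-level sum inherits the shift and
#' the aggregation step is exercised. Background expression is
#' LogNormal(2, 1); planted expression genes get the class shift on the
#' log scale (a multiplicative shift of the value). Barcodes are
#' syntactically valid aliquots with sample-type code 01 (tumoral) or 11
#' (normal); experiment availability per sample follows `spec@overlap`.
#' Output is byte-identical across runs with the same spec.
#'
#' @param spec a [CohortSpec-class].
#' @param outDir output directory (created; must be empty or absent).
#' @param ... unused.
#' @return list with components `dir`, `manifest` (data.frame: file,
#'   barcode, experiment, class), and `truth` (list: planted genes,
#'   per-sample class and availability).
#' @rdname simulateCohort
#' @export
setMethod("simulateCohort", "CohortSpec", function(spec, outDir, ...) {
  validObject(spec)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

  n <- spec@nTumoral + spec@nNormal
  universe <- geneUniverse(spec@nGenes)
  classes <- c(rep("tumoral", spec@nTumoral), rep("normal", spec@nNormal))

  withSeed(spec@seed, {
    # fixed site annotation shared by all samples
    nSites <- sample(seq(spec@sitesPerGene[1L], spec@sitesPerGene[2L]),
                     spec@nGenes, replace = TRUE)
    siteGene <- rep(universe, nSites)
    siteChrom <- sample(paste0("chr", 1:22), length(siteGene), replace = TRUE)
    siteStart <- sample.int(100000000L, length(siteGene), replace = TRUE)

    # barcodes
    participant <- sprintf("A%03d", seq_len(n))
    trunc <- paste0("TCGA-SY-", participant, "-",
                    ifelse(classes == "tumoral", "01A", "11A"))
    methAliquot <- paste0(trunc, "-11D-", sprintf("A%03d", seq_len(n)), "-05")
    rnaAliquot <- paste0(trunc, "-11R-", sprintf("A%03d", seq_len(n)), "-07")

    # experiment availability
    nBoth <- round(spec@overlap[["both"]] * n)
    nOnlyMeth <- round(spec@overlap[["onlyMeth"]] * n)
    nOnlyRna <- n - nBoth - nOnlyMeth
    status <- c(rep("both", nBoth), rep("onlyMeth", nOnlyMeth),
                rep("onlyRna", nOnlyRna))[sample.int(n)]

    shiftMeth <- spec@effectSize * .BETA_SD
    plantedMethSites <- siteGene %in% spec@plantedMethGenes
    logShiftRna <- spec@effectSize * .EXPR_SDLOG
    plantedRna <- universe %in% spec@plantedRnaGenes

    manifest <- list()
    for (i in seq_len(n)) {
      tumoral <- classes[i] == "tumoral"
      if (status[i] != "onlyRna") {
        beta <- stats::rbeta(length(siteGene), .BETA_SHAPE1, .BETA_SHAPE2)
        if (tumoral) beta[plantedMethSites] <- beta[plantedMethSites] + shiftMeth
        beta <- round(pmin(1, pmax(0, beta)), 4L)
        f <- paste0(methAliquot[i], ".meth.bed")
        data.table::fwrite(
          data.table::data.table(siteChrom, siteStart, siteStart + 1L, "+",
                                 siteGene, beta),
          file.path(outDir, f), sep = "\t", col.names = FALSE, quote = FALSE)
        manifest[[length(manifest) + 1L]] <-
          data.frame(file = f, barcode = methAliquot[i], experiment = "dnaMeth",
                     class = classes[i], stringsAsFactors = FALSE)
      }
      if (status[i] != "onlyMeth") {
        lv <- stats::rnorm(spec@nGenes, .EXPR_MEANLOG, .EXPR_SDLOG)
        if (tumoral) lv[plantedRna] <- lv[plantedRna] + logShiftRna
        value <- round(exp(lv), 4L)
        f <- paste0(rnaAliquot[i], ".rna.tsv")
        data.table::fwrite(data.table::data.table(universe, value),
                           file.path(outDir, f), sep = "\t",
                           col.names = FALSE, quote = FALSE)
        manifest[[length(manifest) + 1L]] <-
          data.frame(file = f, barcode = rnaAliquot[i], experiment = "rnaSeq",
                     class = classes[i], stringsAsFactors = FALSE)
      }
    }
    manifest <- do.call(rbind, manifest)
    data.table::fwrite(manifest, file.path(outDir, "manifest.csv"),
                       quote = FALSE)
    truth <- list(
      planted_meth_genes = spec@plantedMethGenes,
      planted_rna_genes = spec@plantedRnaGenes,
      effect_size = spec@effectSize,
      samples = data.frame(sample = trunc, class = classes,
                           availability = status, stringsAsFactors = FALSE)
    )
    jsonlite::write_json(truth, file.path(outDir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
    list(dir = outDir, manifest = manifest, truth = truth)
  })
})

#' Build per-experiment matrices from a generated (or real) cohort directory
#'
#' Reads each per-sample file listed in the manifest, aggregates
#' site-level methylation to the gene methylation quantity, and
#' assembles one [GeneMatrix-class] per experiment. Class labels are
#' derived from the sample-type code of each barcode.
#'
#' @param dir directory containing the per-sample files and
#'   `manifest.csv` (columns `file`, `barcode`, `experiment`).
#' @param dialect a [fileDialect()].
#' @return list with components `meth` and `rna` (each a
#'   [GeneMatrix-class] or `NULL` when the manifest lists no file of that
#'   experiment).
#' @export
cohortToMatrices <- function(dir, dialect = fileDialect()) {
  manifestPath <- file.path(dir, "manifest.csv")
  if (!file.exists(manifestPath)) {
    stop("no manifest.csv under '", dir, "'", call. = FALSE)
  }
  manifest <- as.data.frame(data.table::fread(manifestPath, colClasses = "character"))
  out <- list(meth = NULL, rna = NULL)
  for (tag in c("dnaMeth", "rnaSeq")) {
    rows <- manifest[manifest$experiment == tag, , drop = FALSE]
    if (!nrow(rows)) next
    perSample <- list()
    labels <- character(0)
    for (i in seq_len(nrow(rows))) {
      bc <- rows$barcode[i]
      path <- file.path(dir, rows$file[i])
      perSample[[bc]] <- if (tag == "dnaMeth") {
        aggregateMethylation(readMethylationFile(path, dialect))
      } else {
        recs <- readExpressionFile(path, dialect)
        stats::setNames(recs$value, recs$gene)
      }
      labels[bc] <- classFromBarcode(parseBarcode(bc))
    }
    m <- buildGeneMatrix(perSample, labels, experimentTag = tag)
    out[[if (tag == "dnaMeth") "meth" else "rna"]] <- m
  }
  out
}
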
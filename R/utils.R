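# helpers shared across modules

#' Evaluate an expression under a temporary RNG seed
#'
#' Seeds the random number generator, evaluates `expr`, and restores the
#' caller's `.Random.seed` afterwards, so seeded entry points never
#' disturb the global RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a sub-seed from a master seed
#'
#' Maps a `(seed, offset)` pair to a deterministic seed kept inside the
#' 32-bit integer range, so every randomized step of a pipeline can use
#' its own stream derived from one master seed.
#'
#' @param seed integer master seed.
#' @param offset integer stream offset.
#' @return integer seed.
#' @export
deriveSeed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2011L + as.integer(offset) %% 2011L
}

# Stratified fold assignment: returns an integer vector of fold ids in 1..k,
# one per sample, each class spread as evenly as possible across folds.
stratifiedFolds <- function(classes, k, seed) {
  classes <- as.character(classes)
  folds <- integer(length(classes))
  withSeed(seed, {
    for (cl in sort(unique(classes))) {
      idx <- which(classes == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Render numeric values for CSV output; NA becomes "?".
renderValues <- function(x) {
  out <- as.character(x)
  out[is.na(x)] <- "?"
  out
}

.assertClassLabels <- function(labels, where = "class labels") {
  bad <- setdiff(unique(as.character(labels[!is.na(labels)])), .CLASS_LEVELS)
  if (length(bad)) {
    stop(where, " must be 'normal' or 'tumoral'; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
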
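#' @importFrom methods new validObject is slot
#' @importFrom stats cor median rnorm runif sd setNames quantile
#' @importFrom utils combn read.delim write.table head modifyList
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to a fixed seed for the duration of `expr` and restores the
#' caller's RNG state afterwards, so seeded internals never perturb user
#' code. All randomness in the package flows through this helper.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Natural ordering of chromosome names
#'
#' Orders chromosome names by the trailing integer of the name when one
#' exists ("Bd1" < "Bd2" < "Bd10"), falling back to lexicographic order for
#' names without a trailing number. Used for chromosomal-order naming and
#' all per-chromosome sorting.
#'
#' @param chroms Character vector of chromosome names.
#' @return Integer ranks usable in `order()`.
#' @export
#' @examples
#' chromNaturalOrder(c("Bd10", "Bd2", "Bd1"))
chromNaturalOrder <- function(chroms) {
  stopifnot(is.character(chroms))
  u <- unique(chroms)
  num <- suppressWarnings(as.numeric(sub("^.*?([0-9]+)$", "\\1", u)))
  num[!grepl("[0-9]+$", u)] <- NA_real_
  prefix <- sub("[0-9]+$", "", u)
  uSorted <- u[order(is.na(num), prefix, num, u)]
  match(chroms, uSorted)  # equal names share a rank
}

# Write a data.frame as a plain TSV (no quoting, no row names) -- the
# package's uniform tabular output format.
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

readTsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
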
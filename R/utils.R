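#' @importFrom stats runif rlnorm setNames approx
#' @importFrom utils write.table read.delim packageVersion head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic operations in the package (synthetic-data generation,
#' genetic-algorithm search) route their randomness through this helper so
#' that a seed fully determines the result without clobbering the user's
#' random stream.
#'
#' @param seed integer scalar.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## TSV writers share one dialect: tab-separated, header row, no quoting,
## no row names -- so repeated runs under one seed are byte-identical.
writeTsv <- function(x, path) {
  write.table(x, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

readTsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}

## Named-vector sanity check used by validation layers.
checkNamedNumeric <- function(x, what, allowNA = FALSE) {
  if (!is.numeric(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop(what, " must be a named numeric vector", call. = FALSE)
  if (!allowNA && any(!is.finite(x)))
    stop(what, " contains non-finite values: ",
         paste(names(x)[!is.finite(x)], collapse = ", "), call. = FALSE)
  invisible(x)
}
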
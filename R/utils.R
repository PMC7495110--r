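# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never disturb the
#' caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seed from a master seed and an index.
# Keeps results < 2^31 so the value is a valid R integer.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

#' Standardize matrix rows to zero mean and unit norm
#'
#' After this transform the Pearson correlation between two original rows is
#' the plain dot product of the standardized rows, which is what the
#' correlation-distance clustering machinery relies on.
#'
#' @keywords internal
#' @noRd
row_standardize <- function(x) {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  xc <- x - mu
  nrm <- sqrt(rowSums(xc^2))
  if (any(nrm == 0)) {
    stopf("row_standardize: constant row(s) %s have no correlation structure",
          paste(utils::head(which(nrm == 0), 5L), collapse = ", "))
  }
  xc / nrm
}
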
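#' @importFrom stats rnbinom rpois runif rgamma sd var cor quantile prcomp
#'   kmeans dist p.adjust lm coef pnorm setNames complete.cases aggregate
#' @importFrom utils combn read.delim write.table read.csv write.csv
#' @importFrom methods as is
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers never perturb the
#' caller's RNG stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Deterministic non-negative integer hash of a label string, used to key
# per-cluster seeds by label rather than by position.
label_hash <- function(label) {
  bytes <- as.integer(charToRaw(as.character(label)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 1000003
  h
}

# Coerce any matrix-like input to a numeric general CsparseMatrix.
coerce_sparse <- function(m) {
  if (!inherits(m, "Matrix")) {
    m <- Matrix::Matrix(as.matrix(m) + 0, sparse = TRUE)
  }
  as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
}
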
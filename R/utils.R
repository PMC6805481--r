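#' @keywords internal
"_PACKAGE"

#' @importFrom stats var cor rnorm runif rbinom rbeta rpois pchisq coef lm
#'   model.matrix sd aggregate complete.cases setNames na.omit prcomp qnorm
#' @importFrom utils write.csv read.csv
#' @import Matrix
NULL

## internal assertion helper: stop with caller-friendly message
.check <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
  invisible(TRUE)
}

.is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

.is_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Derive a child seed from a master seed and a label
#'
#' Deterministic hash of `label:master` into the 32-bit integer range, used
#' to give every scenario / replicate its own reproducible stream without
#' touching the global RNG state.
#'
#' @param master integer master seed.
#' @param label character tag for the consumer.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, label) {
  bytes <- utils::head(charToRaw(paste0(label, ":", master)), 64L)
  h <- 0
  for (b in as.integer(bytes)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' Evaluate an expression under a local RNG state
#'
#' Seeds the generator, runs `expr`, and restores the previous global RNG
#' state afterwards.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## symmetrize a nearly-symmetric matrix (guards numerical asymmetry)
.symmetrize <- function(M) (M + t(M)) / 2
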
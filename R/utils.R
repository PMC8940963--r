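#' @keywords internal
"_PACKAGE"

#' @importFrom stats rpois runif rnorm rgamma sd var median t.test wilcox.test
#'   dnorm complete.cases setNames quantile aggregate cor
#' @importFrom utils write.csv read.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0))
    stopf("'%s' must be a %s scalar", name,
          if (strict) "positive" else "non-negative")
  invisible(x)
}

#' Derive a stream-specific seed from a master seed
#'
#' Deterministic sub-seeds keep independent pipeline stages reproducible
#' without sharing one RNG stream.  Kept below 2^31.
#' @param seed master integer seed
#' @param stream small integer offset identifying the consumer
#' @keywords internal
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream) * 9176L) %% 2147483629L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
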
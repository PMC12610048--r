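#' @importFrom methods is
#' @importFrom stats rbinom rpois runif median setNames
#' @importFrom utils write.table read.table packageVersion
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All randomness in this package flows through here: no function
# touches the global stream implicitly.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Random DNA of a given length and GC fraction, as a character scalar.
random_dna <- function(n, gc = 0.5) {
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
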
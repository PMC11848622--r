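# Internal helpers shared across modules.

# Run `expr` under a local RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package routes through this so a seed
# stored in a config object fully determines the output without touching
# global state.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be a single number", name)
  }
  if (finite && !is.finite(x)) stopf("`%s` must be finite", name)
  if (positive && x <= 0) stopf("`%s` must be positive", name)
  invisible(x)
}

# Standard error of the mean; NA for n = 1 (contract: undefined, not 0).
sem <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  stats::sd(x) / sqrt(n)
}
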
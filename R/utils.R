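# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Coefficient of variation with the n-1 SD denominator used throughout.
cv_of <- function(x) {
  m <- mean(x)
  if (m == 0) {
    return(NA_real_)
  }
  stats::sd(x) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_imdsig <- function(...) stop(..., call. = FALSE)
warn_imdsig <- function(...) warning(..., call. = FALSE)
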
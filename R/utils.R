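# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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
  expr
}

# Deterministic sub-seed derivation: replicate/fold r gets its own stream so
# any replicate is reproducible in isolation. Kept below 2^31 - 1.
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  s <- (abs(seed) %% m) * 48271 %% m
  as.integer((s + index * 2654435 + 12345) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_iprs <- function(...) stop(sprintf(...), call. = FALSE)

# Clamp probabilities strictly inside (0, 1).
clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)
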
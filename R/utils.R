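# Internal helpers: scoped RNG and a portable string hash for per-protein
# deterministic pseudorandomness.

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
# stream.  All exported stochastic functions take an explicit seed and go
# through this, so they are pure functions of their arguments.
with_seed <- function(seed, expr) {
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

# Deterministic 31-bit hash of a string combined with an integer seed.
# Multiplier kept small so double-precision arithmetic stays exact
# (h < 2^31, h*31 + 255 < 2^36 < 2^53).
string_seed <- function(id, seed) {
  mod <- 2147483629
  h <- 5381
  for (b in utf8ToInt(id)) h <- (h * 31 + b) %% mod
  h <- (h * 31 + (as.numeric(seed) %% mod)) %% mod
  as.integer(h)
}

# Derive a child seed (< 2^31) from a parent seed and an index.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 131 + as.numeric(i) * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
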
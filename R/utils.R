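# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(...) {
  stop(..., call. = FALSE)
}

check_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_bad_arg(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stop_bad_arg(sprintf("'%s' must lie in [0, 1]", name))
  x
}

# Derive a reproducible child seed (< 2^31) from a parent seed and a stream tag.
# Single global seed, sub-generators draw their own stream.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 1009) %% 2147483629
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483629))
  }
  force(expr)
}

# Bijections between open intervals and the real line used by the optimizer.
to_corr <- function(z) tanh(z)
from_corr <- function(r) atanh(pmin(pmax(r, -0.9999), 0.9999))
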
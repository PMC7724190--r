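# Small shared helpers.

# Run expr under a temporary seed, restoring the caller's RNG state.
with_preserved_rng <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

# Half-up rounding (floor(x + 0.5)), the convention of the original platform.
round_half_up <- function(x) floor(x + 0.5)

# Discrete uniform draw(s) on {lo, ..., hi}.
d_uniform <- function(n, lo, hi) {
  lo + floor(stats::runif(n) * (hi - lo + 1))
}

# Uniform pick of one element from a vector (avoids sample()'s scalar trap).
pick_one <- function(x) {
  if (length(x) == 0L) return(x)
  x[[1L + floor(stats::runif(1) * length(x))]]
}

# Random permutation of indices 1..n.
shuffled <- function(n) {
  if (n <= 1L) return(seq_len(n))
  sample.int(n)
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
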
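# Shared fixtures: small maps and states built in code.

# A map from a character matrix of 6-digit tokens (rows top to bottom).
map_from_tokens <- function(tokens) {
  paste(apply(tokens, 1, paste, collapse = " "), collapse = "\n")
}

# Uniform map of one repeated token.
uniform_map <- function(token, width = 5, height = 5) {
  map_from_tokens(matrix(token, height, width))
}

# A tiny banded coastal map: 1 row deep sea, 2 nearshore, water's edge,
# coastline, beachfront, beach, inland. 8 columns.
tiny_coast_map <- function() {
  paste(
    "100000 100000 100000 100000 100000 100000 100000 100000",
    "201300 200000 200100 200000 203200 200000 201000 200000",
    "200000 200100 200000 201100 200000 200000 200000 202000",
    "400000 400000 400000 400000 400000 400000 400000 400000",
    "500000 500000 500000 500000 500000 500000 500000 500000",
    "608000 600000 650000 600000 600000 608000 600000 600000",
    "610000 610000 660000 610000 610000 610000 610000 610000",
    "990000 990000 990000 990000 990000 990000 990000 990000",
    sep = "\n")
}

default_test_map <- function(seed = 1) generate_synthetic_map(30, 30, seed)

# A fully initialised state on the standard synthetic map.
make_state <- function(seed = 42, map = default_test_map(), ...) {
  coast_setup(coast_params(seed_for_random = seed, ...), map)
}

# Reduce a state to two named living operators placed on given cells, with
# controlled budgets; used by the action tests.
isolate_two_ops <- function(state, cell_a, cell_b, resources = 10,
                            maxc = 10) {
  keep <- which(state$ops$alive & !state$ops$mobile)[1:2]
  state$ops$alive[] <- FALSE
  state$ops$alive[keep] <- TRUE
  state$ops$loc[keep] <- c(cell_a, cell_b)
  state$ops$base[keep] <- c(cell_a, cell_b)
  state$ops$resources[keep] <- resources
  state$ops$alloc[keep, ] <- 0L
  state$ops$maxc[keep] <- maxc
  state$ops$wpos[keep, "s"] <- 1L
  state$links[] <- NA_real_
  list(state = state, ids = keep)
}

# 3-sigma binomial check helper.
expect_binomial <- function(successes, n, p) {
  expect_lt(abs(successes / n - p), 3 * sqrt(p * (1 - p) / n) + 1e-12)
}
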
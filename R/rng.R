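# Named RNG substreams so that spawning, Brownian kicks, and each scripted
# player draw from independent reproducible sequences: swapping one player's
# policy cannot perturb the randomness seen by the others.

#' Derive a child seed from a root seed and integer tags
#'
#' Deterministic integer mixing used to give every substream (spawn, Brownian
#' forces, per-player policies, per-trial replicates) its own seed. The result
#' is always in `[1, 2^31 - 2]`.
#'
#' @param seed Integer root seed.
#' @param ... Integer tags (e.g. cell index, replicate index, stream id).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime; all arithmetic stays < 2^53
  h <- as.numeric(seed) %% m
  for (k in c(...)) {
    h <- (h * 69069 + (as.numeric(k) + 1) * 40503) %% m
    h <- (h * 69069 + 12345) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

# A substream is an environment carrying a saved .Random.seed state.
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  e
}

# Evaluate a sampling function under a substream, advancing only that stream.
stream_do <- function(stream, f, ...) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  res <- f(...)
  stream$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  res
}
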
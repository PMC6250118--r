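# Seed plumbing: one user-facing seed per run, with per-component streams
# derived deterministically so that toggling one randomized component does
# not shift the draws of another.

#' Derive a component seed from a run seed and a label
#'
#' Deterministic 31-bit hash of `(seed, label)`. Used internally so weight
#' initialization, stimulus encoding, dataset generation and shuffling each
#' consume an independent stream.
#'
#' @param seed integer run seed.
#' @param label character component label.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 1L) + 1L)
}

# Seed the global RNG, returning a handle whose $restore() puts the previous
# RNG state back. Keeps component streams from leaking into user code.
local_rng <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
}
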
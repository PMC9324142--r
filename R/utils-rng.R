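#' Evaluate code with a locally seeded RNG
#'
#' Saves and restores `.Random.seed` so that simulation code never leaks RNG
#' state into the caller's session. All randomness in the package flows
#' through this helper from one explicit user-supplied seed.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a child seed from a parent seed and a stream label
#'
#' Deterministic splitting: the same (seed, labels) always yields the same
#' child seed, distinct labels yield (practically) distinct streams. Result
#' stays below 2^31 so it is a valid R integer seed.
#'
#' @param seed parent integer seed.
#' @param ... character or numeric stream labels.
#' @return integer child seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(seed) %% m
  for (tok in list(...)) {
    for (ch in utf8ToInt(paste0("/", as.character(tok)))) {
      h <- (h * 131 + ch) %% m
    }
  }
  as.integer(h)
}
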
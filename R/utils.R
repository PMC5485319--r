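# Internal utilities: seeded RNG scoping and seed derivation.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded generators are pure
#' functions of their seed and do not disturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    old <- get(".Random.seed", envir = env)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% 2147483647))
  code
}

#' Derive a child seed from a master seed
#'
#' All random consumers in an experiment (phantom generation, motion sampling,
#' feature-spec sampling, dataset pairing, fold shuffling, forest training)
#' receive independent child seeds derived from one master seed by this
#' documented rule: a Lehmer-style fold of the master seed with a sequence of
#' stream identifiers, modulo 2^31 - 1. Deterministic and collision-unlikely
#' for the small identifier sets used here.
#'
#' @param master Integer master seed.
#' @param ... Integer stream identifiers (at least one).
#' @return An integer in \code{[1, 2^31 - 2]}.
#' @export
derive_seed <- function(master, ...) {
  ids <- c(...)
  stopifnot(length(ids) >= 1)
  s <- as.double(master) %% 2147483647
  for (id in ids) {
    s <- (s * 48271 + as.double(id) + 1) %% 2147483647
  }
  as.integer(s %% 2147483646 + 1)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}
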
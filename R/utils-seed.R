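#' Derive a reproducible sub-seed from a master seed
#'
#' Mixes a master seed with an arbitrary number of integer or character
#' tags into a new seed in `[1, 2^31 - 2]`. Used throughout the package so
#' that every stochastic stage (cohort synthesis, fold shuffling, weight
#' initialization, minibatch order) is a pure function of one master seed.
#'
#' @param seed integer master seed.
#' @param ... integer or character tags identifying the consumer
#'   (e.g. participant index, vocalization type, replicate number).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483629 # prime < 2^31
  h <- as.numeric(seed) %% m
  for (tag in list(...)) {
    if (is.character(tag)) {
      tag <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
    }
    for (v in as.numeric(tag)) {
      h <- (h * 48271 + (v %% m) + 11) %% m
    }
  }
  as.integer(h %% (m - 2) + 1)
}

#' Run an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so library code does not
#' disturb user-level random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
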
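#' @importFrom rlang abort warn .data hash
#' @importFrom dplyr %>%
NULL

# Run code under a local RNG state seeded with `seed`; the caller's RNG
# stream is restored afterwards so package functions never perturb it.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a child seed from a base seed and a stream label; keeps every
# stage of the pipeline on its own reproducible stream below 2^31.
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- strtoi(substr(rlang::hash(list(as.integer(seed), stream)), 1, 7), 16L)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_prob <- function(x, name = deparse(substitute(x))) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must contain probabilities in [0, 1].", name))
  }
  invisible(x)
}
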
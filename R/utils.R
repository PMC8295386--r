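# Seed plumbing. Functions that accept `seed` set the RNG locally and
# restore the caller's state, so library code never clobbers a user session.

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Derive a reproducible child seed
#'
#' Hierarchical seed splitting: one master seed in a configuration is
#' deterministically combined with integer indices (participant, run,
#' stage ...) so that parallel units never share a stream and reruns are
#' bit-identical. Uses a multiplicative hash over the indices modulo
#' 2^31 - 19 (a prime below the 32-bit integer ceiling).
#'
#' @param seed master integer seed.
#' @param ... integer indices identifying the unit.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483629            # 2^31 - 19, prime
  x <- as.numeric(seed) %% m
  for (i in idx) {
    x <- (x * 69069 + as.numeric(i) + 1) %% m
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
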
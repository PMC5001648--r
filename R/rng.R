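#' Derive a child seed from a master seed
#'
#' Experiments fan out into many independently seeded draws (one per vertex,
#' array, realisation, ...). Children are derived deterministically from the
#' master seed and a list of integer/character tags, and always lie in
#' `[1, 2^31 - 2]` so they are valid R seeds on all platforms.
#'
#' @param seed master seed (single non-negative integer-valued number).
#' @param ... integer or character tags identifying the child stream.
#' @return a single integer seed.
#' @export
child_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed), seed >= 0)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (part in list(...)) {
    if (is.character(part)) {
      part <- sum(utf8ToInt(paste(part, collapse = "|"))) %% m
    }
    for (x in as.numeric(part)) {
      # 16-bit split keeps every product below 2^47 < 2^53 (exact doubles)
      lo <- h %% 65536
      hi <- (h - lo) / 65536
      h <- (hi * 48271 %% m * 65536 + lo * 48271 + x %% m + 104729) %% m
    }
  }
  as.integer(h %% (m - 2)) + 1L
}

#' Evaluate code under a temporary RNG state
#'
#' Sets R's RNG to `seed`, evaluates `code`, and restores the caller's
#' RNG state afterwards.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Seeded Gaussian white-noise matrix
#'
#' Fast generator used for the sensor-noise term of simulated recordings.
#' Fully deterministic given `seed`; independent of R's RNG state.
#'
#' @param nrow,ncol matrix dimensions.
#' @param sd standard deviation.
#' @param seed non-negative integer seed.
#' @return `nrow` x `ncol` numeric matrix of i.i.d. N(0, sd^2) draws.
#' @export
noise_matrix <- function(nrow, ncol, sd, seed) {
  .noise_matrix(as.integer(nrow), as.integer(ncol), as.numeric(sd),
                as.numeric(seed))
}
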
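# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that simulation helpers are
#' reproducible without clobbering the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  has_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = env, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Cross product of two 3-vectors
#' @noRd
cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' Row-wise Euclidean norms of a matrix
#' @noRd
row_norms <- function(m) sqrt(rowSums(m * m))

#' Check that `x` is a single finite number
#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Coerce seconds to a sample index range (1-based, clipped)
#' @noRd
window_to_samples <- function(start_s, end_s, rate_hz, n) {
  i0 <- max(1L, floor(start_s * rate_hz) + 1L)
  i1 <- min(n, ceiling(end_s * rate_hz))
  c(i0, i1)
}
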
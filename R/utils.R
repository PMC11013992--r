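# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded operations never perturb user randomness.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' @noRd
stop_dfseg <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop_dfseg("`%s` must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

#' Squared Euclidean distances from one point to a set of points
#' @noRd
sqdist_to <- function(coords, p) {
  d1 <- coords[, 1L] - p[1L]
  d2 <- coords[, 2L] - p[2L]
  d3 <- coords[, 3L] - p[3L]
  d1 * d1 + d2 * d2 + d3 * d3
}
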
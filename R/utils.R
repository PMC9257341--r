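#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded generators have no side effects on the
#' global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer")
  }
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Integer pixel offsets of a Euclidean disk
#'
#' All integer offsets (dx, dy) with dx^2 + dy^2 <= r^2, ordered by squared
#' distance. A radius-2 disk has 13 offsets.
#'
#' @param r disk radius in pixels (>= 0).
#' @return data.frame with columns dx, dy, d2.
#' @keywords internal
disk_offsets <- function(r) {
  if (r < 0) stop("radius must be non-negative")
  s <- seq(-floor(r), floor(r))
  g <- expand.grid(dx = s, dy = s)
  g$d2 <- g$dx^2 + g$dy^2
  g <- g[g$d2 <= r^2, , drop = FALSE]
  g[order(g$d2, g$dy, g$dx), , drop = FALSE]
}

stopifnot_2d <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("%s must be a 2-D numeric matrix", what))
  }
}

is_binary <- function(x) all(x %in% c(0, 1))
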
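# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_binary <- function(m) is.matrix(m) && all(m %in% c(0, 1))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Rotate a matrix by a multiple of 90 degrees
#'
#' Exact (interpolation-free) rotation used for the thermal-frame
#' rotation-merge strategy. Positive `k` rotates counter-clockwise, as in
#' the usual mathematical convention with the image origin top-left.
#'
#' @param m a matrix.
#' @param k integer number of 90 degree counter-clockwise turns (may be
#'   negative).
#' @return the rotated matrix.
#' @export
rot90_mat <- function(m, k = 1L) {
  stopifnot(is.matrix(m))
  k <- ((as.integer(k) %% 4L) + 4L) %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[ncol(m):1L, , drop = FALSE]
  m
}

# run code with an isolated, seeded RNG stream and restore the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
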
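#' Select feature points on the processed reference
#'
#' Shi-Tomasi corner selection: the corner response is the smaller
#' eigenvalue of the windowed gradient structure tensor. Corners above a
#' quality fraction of the strongest response are sorted by response and
#' kept greedily subject to a minimum pairwise distance, capped at `n_max`;
#' only points inside the body mask (and far enough from the frame border
#' for the tracking window) are retained.
#'
#' @param ref a [compose_reference()] result (or a plain matrix plus
#'   `mask`).
#' @param n_max maximum number of corners (default 90).
#' @param min_distance minimum pairwise distance at selection (default 10).
#' @param quality corners weaker than `quality * max(response)` are
#'   discarded (default 0.01).
#' @param mask optional binary matrix when `ref` is a plain matrix.
#' @param border margin (px) excluded around the frame; defaults to half
#'   the tracking window plus 2.
#' @return an object of class `track_set` with 0-based `(x, y)` positions.
#' @export
select_features <- function(ref, n_max = 90L, min_distance = 10,
                            quality = 0.01, mask = NULL, border = 12L) {
  if (inherits(ref, "processed_reference")) {
    img <- ref$image
    mask <- ref$mask$raster
  } else {
    img <- ref
  }
  stopifnot(is.matrix(img), n_max >= 1L)
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  nr <- nrow(img); nc <- ncol(img)
  R <- corner_response(img)
  if (!is.null(mask)) R[mask == 0] <- 0
  b <- max(2L, as.integer(border))
  R[c(seq_len(min(b, nr)), max(1L, nr - b + 1L):nr), ] <- 0
  R[, c(seq_len(min(b, nc)), max(1L, nc - b + 1L):nc)] <- 0
  maxR <- max(R)
  empty <- structure(list(pts = matrix(numeric(0), 0L, 2L),
                          scores = numeric(0), traj = NULL, status = NULL,
                          timebase = NA_real_),
                     class = "track_set")
  if (maxR <= 0) return(empty)
  R[R < quality * maxR] <- 0
  # non-maximum suppression over the 8-neighbourhood
  nm <- R
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    sh <- matrix(-Inf, nr, nc)
    rs <- seq_len(nr) + di; cs <- seq_len(nc) + dj
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    sh[ok_r, ok_c] <- R[rs[ok_r], cs[ok_c]]
    nm[sh > nm] <- 0
  }
  cand <- which(nm > 0, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  sc <- nm[cand]
  ord <- order(sc, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  sc <- sc[ord]
  keep_x <- numeric(0); keep_y <- numeric(0); keep_s <- numeric(0)
  md2 <- min_distance^2
  for (i in seq_len(nrow(cand))) {
    x <- cand[i, 2L] - 1; y <- cand[i, 1L] - 1  # 0-based
    if (length(keep_x) &&
        any((keep_x - x)^2 + (keep_y - y)^2 < md2)) next
    keep_x <- c(keep_x, x); keep_y <- c(keep_y, y); keep_s <- c(keep_s, sc[i])
    if (length(keep_x) >= n_max) break
  }
  structure(list(pts = cbind(x = keep_x, y = keep_y), scores = keep_s,
                 traj = NULL, status = NULL, timebase = NA_real_),
            class = "track_set")
}

# min-eigenvalue (Shi-Tomasi) corner response: Sobel gradients, 3x3
# box-summed structure tensor
corner_response <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  shift <- function(m, di, dj) {
    out <- matrix(0, nr, nc)
    rs <- seq_len(nr) + di; cs <- seq_len(nc) + dj
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  gx <- (shift(img, -1, 1) + 2 * shift(img, 0, 1) + shift(img, 1, 1)) -
        (shift(img, -1, -1) + 2 * shift(img, 0, -1) + shift(img, 1, -1))
  gy <- (shift(img, 1, -1) + 2 * shift(img, 1, 0) + shift(img, 1, 1)) -
        (shift(img, -1, -1) + 2 * shift(img, -1, 0) + shift(img, -1, 1))
  box <- function(m) {
    out <- matrix(0, nr, nc)
    for (di in -1:1) for (dj in -1:1) out <- out + shift(m, di, dj)
    out
  }
  sxx <- box(gx * gx); syy <- box(gy * gy); sxy <- box(gx * gy)
  tr <- sxx + syy
  disc <- sqrt(pmax((sxx - syy)^2 + 4 * sxy^2, 0))
  (tr - disc) / 2
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d points%s\n", nrow(x$pts),
              if (is.null(x$traj)) " (not yet tracked)"
              else sprintf(", tracked over %d steps", dim(x$traj)[1L] - 1L)))
  invisible(x)
}

#' Track feature points through a frame sequence
#'
#' Pyramidal Lucas-Kanade sparse optical flow: each selected point's
#' displacement between consecutive frames is the least-squares solution
#' of the brightness-constancy equations over a fixed window, refined
#' coarse-to-fine over an image pyramid. The previous step's displacement
#' warm-starts the next solve. Points whose solve fails, whose window
#' leaves the image, or whose gradient matrix is degenerate are flagged
#' invalid from that step onward. Frames after the first are used as plain
#' grayscale (no reference preprocessing).
#'
#' @param tracks a [select_features()] result.
#' @param frames a [frame_sequence] (>= 2 frames, grayscale).
#' @param window odd LK window size (default 21).
#' @param max_level number of pyramid reductions (default 3, i.e. up to 4
#'   pyramid images).
#' @param max_iter,eps iteration cap and termination threshold.
#' @param min_eig minimum normalized eigenvalue of the gradient matrix for
#'   a solve to count as well-posed.
#' @return the `track_set` with `traj` (`(n_frames) x n x 2` array of
#'   0-based positions) and `status` (validity per frame per point).
#' @export
track_points <- function(tracks, frames, window = 21L, max_level = 3L,
                         max_iter = 30L, eps = 0.01, min_eig = 1e-4) {
  stopifnot(inherits(tracks, "track_set"), inherits(frames, "frame_sequence"))
  n_frames <- length(frames$frames)
  if (n_frames < 2L) stopf("tracking requires at least 2 frames")
  if (frame_channels(frames$frames[[1L]]) != 1L)
    stopf("tracking expects grayscale frames; convert with gray_sequence()")
  n <- nrow(tracks$pts)
  traj <- array(NA_real_, dim = c(n_frames, n, 2L))
  status <- matrix(FALSE, n_frames, n)
  if (n == 0L) {
    tracks$traj <- traj; tracks$status <- status
    tracks$timebase <- frames$timebase
    return(tracks)
  }
  res <- .lk_track(frames$frames, tracks$pts, win = as.integer(window),
                   max_level = as.integer(max_level),
                   max_iter = as.integer(max_iter), eps = eps,
                   min_eig = min_eig)
  traj[, , 1L] <- res$x
  traj[, , 2L] <- res$y
  status <- res$status
  tracks$traj <- traj
  tracks$status <- status
  tracks$timebase <- frames$timebase
  tracks
}

#' Export trajectories as a data frame
#'
#' @param x a tracked `track_set`.
#' @param ... unused.
#' @return data frame with columns `point_id`, `t`, `x`, `y`, `valid`,
#'   `dx`, `dy` (per-frame displacements; `NA` where invalid).
#' @export
as.data.frame.track_set <- function(x, ...) {
  if (is.null(x$traj)) stopf("track_set has not been tracked yet")
  nf <- dim(x$traj)[1L]; n <- dim(x$traj)[2L]
  out <- data.frame(
    point_id = rep(seq_len(n), each = nf),
    t = rep(seq_len(nf) - 1L, times = n),
    x = as.vector(x$traj[, , 1L]),
    y = as.vector(x$traj[, , 2L]),
    valid = as.vector(x$status))
  dx <- apply(x$traj[, , 1L, drop = FALSE], 2L, function(v) c(NA, diff(v)))
  dy <- apply(x$traj[, , 2L, drop = FALSE], 2L, function(v) c(NA, diff(v)))
  out$dx <- as.vector(dx)
  out$dy <- as.vector(dy)
  out
}
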
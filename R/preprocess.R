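#' Modality configuration
#'
#' The three values in which the visible-light and thermal configurations
#' differ, plus the tracking/classifier parameters shared by both. The
#' defaults are the pipeline's standard operating points: an 80 px grid
#' with histogram equalization and relevant-magnitude threshold M = 100 for
#' RGB; a 40 px grid, no equalization and M = 450 for IRT (where the person
#' mask is additionally merged over 0/+90/-90 degree frame rotations).
#'
#' @param modality `"rgb"` or `"irt"`.
#' @param ... overrides for any field: `grid_spacing`, `equalize`,
#'   `magnitude_threshold`, `n_max`, `min_distance`, `lk_window`,
#'   `lk_max_level`, `lk_max_iter`, `lk_eps`, `T_steps`, `peak_threshold`,
#'   `detection_threshold`, `rotations`.
#' @return an object of class `modality_config`.
#' @export
modality_config <- function(modality = c("rgb", "irt"), ...) {
  modality <- match.arg(modality)
  cfg <- list(
    modality = modality,
    grid_spacing = if (modality == "rgb") 80L else 40L,
    equalize = modality == "rgb",
    magnitude_threshold = if (modality == "rgb") 100 else 450,
    n_max = 90L,
    min_distance = 10,
    lk_window = 21L,
    lk_max_level = 3L,
    lk_max_iter = 30L,
    lk_eps = 0.01,
    T_steps = 30L,
    peak_threshold = 3L,
    detection_threshold = 0.7,
    rotations = if (modality == "rgb") 0 else c(0, 90, -90)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("unknown config field(s): %s", paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  if (cfg$grid_spacing <= 0 || cfg$magnitude_threshold <= 0)
    stopf("grid_spacing and magnitude_threshold must be positive")
  structure(cfg, class = "modality_config")
}

#' Binary erosion and dilation
#'
#' Strict set-semantics morphology on binary rasters: the erosion of A by
#' structuring element B is the set of translations z with B translated by
#' z contained in A; the dilation is the set of translations where the
#' reflection of B overlaps A. Pixels outside the raster are background.
#' The structuring element is a 0/1 matrix with odd dimensions; its origin
#' is the central cell.
#'
#' @param A binary matrix.
#' @param B structuring element (binary matrix, odd dimensions, nonempty).
#' @return binary matrix of the same shape as `A`.
#' @export
binary_erode <- function(A, B = matrix(1, 3, 3)) {
  morph(A, B, erode = TRUE)
}

#' @rdname binary_erode
#' @export
binary_dilate <- function(A, B = matrix(1, 3, 3)) {
  morph(A, B, erode = FALSE)
}

morph <- function(A, B, erode) {
  if (!is_binary(A)) stopf("A must be a binary (0/1) matrix")
  if (!is.matrix(B) || sum(B != 0) == 0L) stopf("structuring element must be nonempty")
  if (nrow(B) %% 2L == 0L || ncol(B) %% 2L == 0L)
    stopf("structuring element must have odd dimensions")
  oy <- (nrow(B) + 1L) %/% 2L; ox <- (ncol(B) + 1L) %/% 2L
  offs <- which(B != 0, arr.ind = TRUE)
  nr <- nrow(A); nc <- ncol(A)
  out <- matrix(if (erode) 1L else 0L, nr, nc)
  for (k in seq_len(nrow(offs))) {
    di <- offs[k, 1L] - oy; dj <- offs[k, 2L] - ox
    if (!erode) { di <- -di; dj <- -dj }  # dilation uses the reflected SE
    sh <- matrix(0L, nr, nc)
    rs <- seq_len(nr) + di; cs <- seq_len(nc) + dj
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    sh[ok_r, ok_c] <- A[rs[ok_r], cs[ok_c]]
    out <- if (erode) out * sh else pmax(out, sh)
  }
  out
}

# Guo-Hall two-subfield thinning lookup tables, built from the published
# deletion conditions G1 (single crossing), G2 (neighbour count) and
# G3/G3' (subfield-specific edge conditions). Bit i of the code is the
# neighbour at offset: 0:E 1:NE 2:N 3:NW 4:W 5:SW 6:S 7:SE.
thinning_luts <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g1 <- g2 <- g3 <- g3p <- logical(256L)
    for (n in 0:255) {
      b <- as.integer(intToBits(n))[1:8]
      s <- 0L
      for (i in c(0L, 2L, 4L, 6L)) {
        if (!b[i + 1L] && (b[(i + 1L) %% 8L + 1L] || b[(i + 2L) %% 8L + 1L]))
          s <- s + 1L
      }
      g1[n + 1L] <- s == 1L
      n1 <- 0L; n2 <- 0L
      for (k in c(1L, 3L, 5L, 7L)) {
        if (b[k + 1L] || b[k]) n1 <- n1 + 1L
        if (b[k + 1L] || b[(k + 1L) %% 8L + 1L]) n2 <- n2 + 1L
      }
      g2[n + 1L] <- min(n1, n2) %in% c(2L, 3L)
      g3[n + 1L]  <- !((b[2L] || b[3L] || !b[8L]) && b[1L])
      g3p[n + 1L] <- !((b[6L] || b[7L] || !b[4L]) && b[5L])
    }
    cache <<- list(g1 & g2 & g3, g1 & g2 & g3p)
    cache
  }
})

#' Skeletonize a binary mask
#'
#' Morphological thinning to a one-pixel-wide, topology-preserving medial
#' structure (Guo-Hall two-subfield parallel thinning). Connected
#' components and holes of the mask are preserved; an empty mask yields an
#' empty skeleton.
#'
#' @param mask binary matrix.
#' @return binary matrix: the skeleton (a subset of `mask`).
#' @export
skeletonize_mask <- function(mask) {
  if (!is_binary(mask)) stopf("mask must be a binary (0/1) matrix")
  nr <- nrow(mask); nc <- ncol(mask)
  if (sum(mask) == 0L) return(matrix(0L, nr, nc))
  luts <- thinning_luts()
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  ci <- 2:(nr + 1L); cj <- 2:(nc + 1L)
  n_old <- -1L; n_new <- sum(pad)
  while (n_old != n_new) {
    n_old <- n_new
    for (lut in luts) {
      code <- pad[ci, cj + 1L] + pad[ci - 1L, cj + 1L] * 2L +
        pad[ci - 1L, cj] * 4L + pad[ci - 1L, cj - 1L] * 8L +
        pad[ci, cj - 1L] * 16L + pad[ci + 1L, cj - 1L] * 32L +
        pad[ci + 1L, cj] * 64L + pad[ci + 1L, cj + 1L] * 128L
      D <- matrix(lut[code + 1L], nr, nc)
      sub <- pad[ci, cj]
      sub[D] <- 0L
      pad[ci, cj] <- sub
    }
    n_new <- sum(pad)
  }
  pad[ci, cj, drop = FALSE]
}

#' Overlay a white grid
#'
#' Sets rows and columns at 0-based indices `k * spacing` (k >= 1) to
#' `line_value`, leaving all other pixels unchanged. The grid seeds corner
#' structure inside otherwise homogeneous body regions.
#'
#' @param gray numeric matrix.
#' @param spacing grid pitch in pixels (>= 2).
#' @param line_value intensity of the grid lines (default 255).
#' @param thickness line thickness in pixels (default 1).
#' @return the gridded raster.
#' @export
overlay_grid <- function(gray, spacing, line_value = 255, thickness = 1L) {
  stopifnot(is.matrix(gray))
  if (spacing < 2) stopf("grid spacing must be >= 2")
  nr <- nrow(gray); nc <- ncol(gray)
  lines_at <- function(n) {
    if (spacing > n - 1L) return(integer(0L))
    ks <- seq.int(spacing, n - 1L, by = spacing)  # 0-based line anchors
    if (length(ks) == 0L) return(integer(0L))
    idx <- as.vector(outer(ks, 0:(thickness - 1L), "+")) + 1L
    idx[idx <= n]
  }
  r <- lines_at(nr); cc <- lines_at(nc)
  if (length(r)) gray[r, ] <- line_value
  if (length(cc)) gray[, cc] <- line_value
  gray
}

#' Histogram equalization
#'
#' The classical CDF remapping `T(k) = floor((L - 1) * CDF(k))` computed
#' over the full raster; monotone non-decreasing in the input intensity.
#'
#' @param f integer-valued matrix with intensities in `[0, L - 1]`.
#' @param L number of gray levels (default 256).
#' @return the equalized raster.
#' @export
equalize_hist <- function(f, L = 256L) {
  stopifnot(is.matrix(f))
  if (any(f < 0) || any(f > L - 1) || any(f != floor(f)))
    stopf("intensities must be integers in [0, %d]", L - 1L)
  counts <- tabulate(as.vector(f) + 1L, nbins = L)
  cdf <- cumsum(counts) / length(f)
  map <- floor((L - 1L) * cdf)
  out <- matrix(map[f + 1L], nrow(f), ncol(f))
  storage.mode(out) <- "integer"
  out
}

#' Compose the processed reference frame
#'
#' Builds the raster on which feature points are selected: (1) the white
#' grid is overlaid on the gray frame; (2) the result is multiplied by the
#' binary person mask, zeroing everything outside the body; (3) the mask's
#' skeleton is painted white; (4) for configurations with `equalize = TRUE`
#' (visible light), histogram equalization is applied to the result.
#' Thermal configurations skip step 4.
#'
#' @param gray single-channel numeric matrix (the reference frame).
#' @param mask a [body_mask] (or binary matrix).
#' @param config a [modality_config()].
#' @return an object of class `processed_reference`: list with `image`,
#'   `mask` and `skeleton`.
#' @export
compose_reference <- function(gray, mask, config) {
  stopifnot(is.matrix(gray), inherits(config, "modality_config"))
  m <- if (inherits(mask, "body_mask")) mask$raster else mask
  if (!identical(dim(m), dim(gray))) stopf("mask and frame shapes differ")
  if (sum(m) == 0L) stopf("empty mask: no person region to process")
  skel <- skeletonize_mask(m)
  img <- overlay_grid(gray, config$grid_spacing)
  img <- img * m
  img[skel == 1L] <- 255
  if (isTRUE(config$equalize)) img <- equalize_hist(round(img))
  structure(list(image = img,
                 mask = if (inherits(mask, "body_mask")) mask
                        else body_mask(m, source = "truth"),
                 skeleton = skel),
            class = "processed_reference")
}

#' @export
print.processed_reference <- function(x, ...) {
  cat(sprintf("<processed_reference> %dx%d, %d mask px, %d skeleton px\n",
              nrow(x$image), ncol(x$image), sum(x$mask$raster), sum(x$skeleton)))
  invisible(x)
}
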
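#' Construct a frame sequence
#'
#' A `frame_sequence` is the ordered raster container the whole pipeline
#' consumes: single-channel matrices (grayscale) or height x width x 3
#' arrays (colour), all sharing shape and bit depth, with a time base in
#' seconds per frame and a modality tag.
#'
#' @param frames list of numeric matrices (gray) or h x w x 3 arrays (colour).
#' @param timebase seconds per frame (> 0).
#' @param modality `"rgb"` or `"irt"`.
#' @param bitdepth 8 or 16; intensities are integers in `[0, 2^bitdepth - 1]`.
#' @return an object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, timebase, modality = c("rgb", "irt"),
                           bitdepth = 8L) {
  modality <- match.arg(modality)
  if (!is.list(frames) || length(frames) == 0L)
    stopf("'frames' must be a non-empty list of rasters")
  if (!is.numeric(timebase) || length(timebase) != 1L || timebase <= 0)
    stopf("'timebase' must be a single positive number (seconds/frame)")
  if (!bitdepth %in% c(8L, 16L)) stopf("'bitdepth' must be 8 or 16")
  d0 <- dim(frames[[1L]])
  for (i in seq_along(frames)) {
    di <- dim(frames[[i]])
    if (length(di) != length(d0) || any(di != d0))
      stopf("frame %d has shape (%s); expected (%s)", i,
            paste(di, collapse = "x"), paste(d0, collapse = "x"))
  }
  structure(list(frames = frames, timebase = timebase, modality = modality,
                 bitdepth = as.integer(bitdepth)),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<frame_sequence> %d frames, %s px, %d-bit %s, %.4g s/frame\n",
              length(x$frames), paste(d, collapse = "x"), x$bitdepth,
              x$modality, x$timebase))
  invisible(x)
}

frame_channels <- function(frame) if (length(dim(frame)) == 3L) dim(frame)[3L] else 1L

#' Read a frame sequence from disk
#'
#' Reads a lexicographically ordered directory of PNG or TIFF frames.
#' 8-bit PNG frames are read as integers in 0..255; 16-bit TIFF frames are
#' preserved at 16 bits. Mixed shapes or depths raise an error naming the
#' offending frame. Video containers (MP4/AVI) are not supported by this
#' build; decode them to a frame directory first.
#'
#' @param path directory of frame files.
#' @param kind `"frame_dir"` (the only supported reader).
#' @param timebase seconds per frame; if `NULL`, taken from the directory's
#'   `index.json` when present, else 1.
#' @param modality `"rgb"`, `"irt"`, or `NULL` to take it from `index.json`
#'   (default `"rgb"`).
#' @return a [frame_sequence].
#' @export
read_frames <- function(path, kind = c("frame_dir", "container"),
                        timebase = NULL, modality = NULL) {
  kind <- match.arg(kind)
  if (kind == "container")
    stopf("video-container input is not supported; extract frames to a directory of PNG/TIFF files first")
  if (!dir.exists(path)) stopf("frame directory '%s' does not exist", path)
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE))
  if (length(files) == 0L) stopf("frame directory '%s' contains no PNG/TIFF frames", path)
  idx_path <- file.path(path, "index.json")
  idx <- if (file.exists(idx_path)) jsonlite::read_json(idx_path) else list()
  timebase <- timebase %||% idx$timebase %||% 1
  modality <- modality %||% idx$modality %||% "rgb"
  bitdepth <- 8L
  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    f <- file.path(path, files[i])
    ext <- tolower(tools::file_ext(f))
    if (ext == "png") {
      v <- png::readPNG(f)
      fr <- round(v * 255)
    } else {
      v <- tiff::readTIFF(f, as.is = TRUE)
      fr <- v
      if (max(v) > 255) bitdepth <- 16L
    }
    if (length(dim(fr)) == 3L && dim(fr)[3L] == 1L) dim(fr) <- dim(fr)[1:2]
    frames[[i]] <- fr
    if (i > 1L && !identical(dim(frames[[i]]), dim(frames[[1L]])))
      stopf("frame '%s' has shape (%s); expected (%s) as in '%s'",
            files[i], paste(dim(fr), collapse = "x"),
            paste(dim(frames[[1L]]), collapse = "x"), files[1L])
  }
  frame_sequence(frames, timebase = timebase, modality = modality,
                 bitdepth = bitdepth)
}

#' Write a frame sequence to a directory
#'
#' Frames are written with zero-padded numeric names. 8-bit sequences go to
#' PNG; 16-bit sequences to 16-bit TIFF. An `index.json` records the time
#' base and modality so [read_frames()] round-trips losslessly.
#'
#' @param fs a [frame_sequence].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_frames <- function(fs, path) {
  stopifnot(inherits(fs, "frame_sequence"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  n <- length(fs$frames)
  fmt <- sprintf("frame_%%0%dd.%s", max(4L, nchar(n)),
                 if (fs$bitdepth == 16L) "tiff" else "png")
  for (i in seq_len(n)) {
    f <- file.path(path, sprintf(fmt, i - 1L))
    fr <- fs$frames[[i]]
    if (fs$bitdepth == 16L) {
      tiff::writeTIFF(fr / 65535, f, bits.per.sample = 16L)
    } else {
      png::writePNG(fr / 255, f)
    }
  }
  jsonlite::write_json(list(timebase = fs$timebase, modality = fs$modality,
                            n_frames = n),
                       file.path(path, "index.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Demosaic a 16-bit Bayer raster to 8-bit RGB
#'
#' Bilinear demosaicing of a single-sensor colour-filter mosaic, followed by
#' linear rescaling to 8 bits by integer division by 256. Border samples are
#' handled by adaptive normalisation (convolution of values divided by
#' convolution of the sampling indicator), so constant fields stay exactly
#' constant.
#'
#' @param raw 16-bit integer matrix with even dimensions.
#' @param pattern Bayer layout of the top-left 2x2 block: `"RGGB"`,
#'   `"BGGR"`, `"GRBG"` or `"GBRG"`.
#' @return h x w x 3 array of 8-bit intensities (0..255).
#' @export
bayer16_to_rgb8 <- function(raw, pattern = c("RGGB", "BGGR", "GRBG", "GBRG")) {
  pattern <- match.arg(pattern)
  stopifnot(is.matrix(raw))
  nr <- nrow(raw); nc <- ncol(raw)
  if (nr %% 2L != 0L || nc %% 2L != 0L)
    stopf("Bayer raster dimensions must be even; got %dx%d", nr, nc)
  if (any(raw < 0) || any(raw > 65535)) stopf("Bayer samples must lie in [0, 65535]")
  # per-site channel layout of the 2x2 tile, row-major
  tiles <- list(RGGB = c("R", "G", "G", "B"), BGGR = c("B", "G", "G", "R"),
                GRBG = c("G", "R", "B", "G"), GBRG = c("G", "B", "R", "G"))
  tile <- matrix(tiles[[pattern]], 2L, 2L, byrow = TRUE)
  odd_r <- (seq_len(nr) - 1L) %% 2L + 1L
  odd_c <- (seq_len(nc) - 1L) %% 2L + 1L
  site <- matrix(tile[cbind(rep(odd_r, nc), rep(odd_c, each = nr))], nr, nc)
  kern_g  <- matrix(c(0, 1, 0, 1, 4, 1, 0, 1, 0), 3, 3)
  kern_rb <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3)
  out <- array(0, dim = c(nr, nc, 3L))
  chans <- c(R = 1L, G = 2L, B = 3L)
  for (ch in names(chans)) {
    ind <- (site == ch) * 1
    kern <- if (ch == "G") kern_g else kern_rb
    num <- conv3(raw * ind, kern)
    den <- conv3(ind, kern)
    out[, , chans[[ch]]] <- num / den
  }
  out <- out %/% 256
  storage.mode(out) <- "integer"
  out
}

# 3x3 zero-padded convolution via shifts (small images; pure R)
conv3 <- function(m, kern) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    w <- kern[di + 2L, dj + 2L]
    if (w == 0) next
    src_r <- clamp(seq_len(nr) + di, 1L, nr); ok_r <- (seq_len(nr) + di) %in% seq_len(nr)
    src_c <- clamp(seq_len(nc) + dj, 1L, nc); ok_c <- (seq_len(nc) + dj) %in% seq_len(nc)
    sh <- matrix(0, nr, nc)
    sh[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
    out <- out + w * sh
  }
  out
}

#' Convert a 3-channel raster to grayscale
#'
#' ITU-R BT.601 luminance combination (weights 0.299, 0.587, 0.114),
#' rounded to the nearest integer.
#'
#' @param frame h x w x 3 numeric array.
#' @return single-channel integer matrix in `[0, 255]` for 8-bit input.
#' @export
to_gray <- function(frame) {
  d <- dim(frame)
  if (length(d) != 3L || d[3L] != 3L)
    stopf("to_gray() expects a 3-channel raster; got %s channel(s)",
          if (length(d) == 3L) d[3L] else 1L)
  g <- round(0.299 * frame[, , 1L] + 0.587 * frame[, , 2L] + 0.114 * frame[, , 3L])
  storage.mode(g) <- "integer"
  g
}

#' Convert every frame of a sequence to grayscale
#'
#' Colour frames go through [to_gray()]; 16-bit single-channel (thermal)
#' frames are linearly rescaled to 8 bits using the per-clip min-max range.
#'
#' @param fs a [frame_sequence].
#' @return a grayscale 8-bit [frame_sequence].
#' @export
gray_sequence <- function(fs) {
  stopifnot(inherits(fs, "frame_sequence"))
  if (frame_channels(fs$frames[[1L]]) == 3L) {
    frames <- lapply(fs$frames, to_gray)
  } else if (fs$bitdepth == 16L) {
    rng <- range(unlist(lapply(fs$frames, range)))
    span <- max(rng[2L] - rng[1L], 1)
    frames <- lapply(fs$frames, function(f) round((f - rng[1L]) / span * 255))
  } else {
    frames <- fs$frames
  }
  frame_sequence(frames, timebase = fs$timebase, modality = fs$modality,
                 bitdepth = 8L)
}
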
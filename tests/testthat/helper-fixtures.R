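# shared fixture builders (all fixtures are generated in code)

# random multi-disc blob mask, deterministic per seed
make_blob_mask <- function(nr = 60, nc = 60, n_discs = 4, r_max = 9, seed = 1) {
  set.seed(seed)
  m <- matrix(0L, nr, nc)
  ys <- sample(seq(r_max + 2, nr - r_max - 1), n_discs, replace = TRUE)
  xs <- sample(seq(r_max + 2, nc - r_max - 1), n_discs, replace = TRUE)
  iy <- row(m); jx <- col(m)
  for (k in seq_len(n_discs)) {
    rad <- sample(3:r_max, 1)
    m[(iy - ys[k])^2 + (jx - xs[k])^2 <= rad^2] <- 1L
  }
  m
}

# smoothed-noise texture with replicate-padded box blur: band-limited
# enough that coarse pyramid levels retain structure, yet a good LK target
make_texture <- function(nr, nc, seed = 7, sd = 120, passes = 4) {
  set.seed(seed)
  m <- matrix(rnorm(nr * nc, 128, sd), nr, nc)
  box <- function(x) {
    n1 <- nrow(x); n2 <- ncol(x)
    up <- x[c(1, 1:(n1 - 1)), ]; dn <- x[c(2:n1, n1), ]
    x <- (up + x + dn) / 3
    lf <- x[, c(1, 1:(n2 - 1))]; rt <- x[, c(2:n2, n2)]
    (lf + x + rt) / 3
  }
  for (i in seq_len(passes)) m <- box(m)
  pmin(pmax(m, 0), 255)
}

# frame sequence of integer translations of a large texture
translation_sequence <- function(shifts, nr = 200, nc = 260, seed = 7,
                                 timebase = 1, sd = 120, passes = 4) {
  pad <- 60
  big <- make_texture(nr + 2 * pad, nc + 2 * pad, seed = seed, sd = sd,
                      passes = passes)
  frames <- lapply(shifts, function(s) {
    big[(1 + pad - s[2]):(nr + pad - s[2]),
        (1 + pad - s[1]):(nc + pad - s[1])]
  })
  frame_sequence(frames, timebase = timebase, modality = "rgb")
}

# direct set-semantics morphology oracle (independent of the implementation)
erode_oracle <- function(A, B) {
  nr <- nrow(A); nc <- ncol(A)
  oy <- (nrow(B) + 1) %/% 2; ox <- (ncol(B) + 1) %/% 2
  offs <- which(B != 0, arr.ind = TRUE)
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ok <- TRUE
    for (k in seq_len(nrow(offs))) {
      ii <- i + offs[k, 1] - oy; jj <- j + offs[k, 2] - ox
      if (ii < 1 || ii > nr || jj < 1 || jj > nc || A[ii, jj] == 0) {
        ok <- FALSE
        break
      }
    }
    out[i, j] <- as.integer(ok)
  }
  out
}

dilate_oracle <- function(A, B) {
  nr <- nrow(A); nc <- ncol(A)
  oy <- (nrow(B) + 1) %/% 2; ox <- (ncol(B) + 1) %/% 2
  offs <- which(B != 0, arr.ind = TRUE)
  out <- matrix(0L, nr, nc)
  for (k in seq_len(nrow(offs))) {
    di <- -(offs[k, 1] - oy); dj <- -(offs[k, 2] - ox)  # reflected SE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && A[ii, jj] != 0)
        out[i, j] <- 1L
    }
  }
  out
}

# independent thinning reference via the installed Python scikit-image;
# all masks are shipped in one process invocation
skimage_thin_batch <- function(masks) {
  tmp_in <- tempfile(fileext = ".txt")
  tmp_py <- tempfile(fileext = ".py")
  con <- file(tmp_in, "w")
  writeLines(as.character(length(masks)), con)
  for (m in masks) {
    writeLines(paste(nrow(m), ncol(m)), con)
    writeLines(paste(as.vector(t(m)), collapse = " "), con)
  }
  close(con)
  writeLines(c(
    "import sys",
    "import numpy as np",
    "from skimage.morphology import thin",
    "with open(sys.argv[1]) as fh:",
    "    k = int(fh.readline())",
    "    for _ in range(k):",
    "        nr, nc = (int(v) for v in fh.readline().split())",
    "        vals = [int(x) for x in fh.readline().split()]",
    "        m = np.array(vals).reshape(nr, nc)",
    "        sk = thin(m > 0).astype(int)",
    "        print(' '.join(str(v) for v in sk.ravel()))"), tmp_py)
  out <- system2("python", c(tmp_py, tmp_in), stdout = TRUE)
  unlink(c(tmp_in, tmp_py))
  lapply(seq_along(masks), function(i) {
    v <- as.integer(strsplit(out[i], " ")[[1]])
    matrix(v, nrow(masks[[i]]), ncol(masks[[i]]), byrow = TRUE)
  })
}

python_available <- function() {
  nzchar(Sys.which("python")) &&
    identical(tryCatch(system2("python", c("-c", shQuote("import skimage")),
                               stdout = FALSE, stderr = FALSE),
                       error = function(e) 1L), 0L)
}
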
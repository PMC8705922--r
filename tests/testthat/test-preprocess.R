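# reference-frame preprocessing: morphology, thinning, grid, equalization

se3 <- matrix(1, 3, 3)

test_that("erosion follows strict set semantics (oracle comparison)", {
  full <- matrix(1L, 8, 10)
  er <- binary_erode(full, se3)
  inner <- matrix(0L, 8, 10)
  inner[2:7, 2:9] <- 1L
  expect_identical(er, inner)  # full raster -> full minus 1-px border

  single <- matrix(0L, 7, 7)
  single[4, 4] <- 1L
  expect_equal(sum(binary_erode(single, se3)), 0)

  set.seed(13)
  for (i in 1:10) {
    A <- matrix(sample(0:1, 15 * 12, TRUE, prob = c(0.3, 0.7)), 15, 12)
    B <- matrix(sample(0:1, 9, TRUE), 3, 3)
    B[2, 2] <- 1
    expect_identical(binary_erode(A, B), erode_oracle(A, B))
    # anti-extensivity when the SE contains its origin
    expect_true(all(binary_erode(A, B) <= A))
  }
})

test_that("dilation follows strict set semantics (oracle comparison)", {
  single <- matrix(0L, 7, 7)
  single[4, 4] <- 1L
  d <- binary_dilate(single, se3)
  expect_equal(sum(d), 9)
  expect_true(all(d[3:5, 3:5] == 1L))

  expect_equal(sum(binary_dilate(matrix(0L, 5, 5), se3)), 0)

  set.seed(14)
  for (i in 1:10) {
    A <- matrix(sample(0:1, 14 * 11, TRUE), 14, 11)
    B <- matrix(sample(0:1, 9, TRUE), 3, 3)
    B[2, 2] <- 1
    expect_identical(binary_dilate(A, B), dilate_oracle(A, B))
    # opening is anti-extensive
    expect_true(all(binary_dilate(binary_erode(A, B), B) <= A))
  }
  expect_error(binary_erode(matrix(1L, 3, 3), matrix(0, 3, 3)), "nonempty")
  expect_error(binary_erode(matrix(1L, 3, 3), matrix(1, 2, 2)), "odd")
})

test_that("skeletonization thins to one-pixel width and preserves topology", {
  # a 1-px line is already thin
  line <- matrix(0L, 9, 9)
  line[5, 2:8] <- 1L
  expect_identical(skeletonize_mask(line), line)

  expect_equal(sum(skeletonize_mask(matrix(0L, 6, 6))), 0)

  # filled rectangle collapses to a medial line
  rect <- matrix(0L, 9, 25)
  rect[3:7, 3:23] <- 1L
  sk <- skeletonize_mask(rect)
  expect_true(all(sk <= rect))            # skeleton within the mask
  expect_lte(max(rowSums(sk)[rowSums(sk) > 0]), 21)
  expect_gte(sum(sk), 15)                 # roughly the medial row
  # 1-px wide: no 2x2 block fully set
  blocks <- sk[-1, -1] + sk[-nrow(sk), -1] + sk[-1, -ncol(sk)] +
    sk[-nrow(sk), -ncol(sk)]
  expect_lt(max(blocks), 4)

  # topology: a ring keeps its hole (skeleton still encircles it)
  ring <- matrix(0L, 21, 21)
  iy <- row(ring) - 11; jx <- col(ring) - 11
  ring[iy^2 + jx^2 <= 81 & iy^2 + jx^2 >= 16] <- 1L
  skr <- skeletonize_mask(ring)
  comp_count <- function(m, eight = TRUE) {
    # flood-fill component count; foreground is 8-connected, background
    # (for hole counting) 4-connected, per the usual duality
    lab <- matrix(0L, nrow(m), ncol(m)); nl <- 0L
    offs <- if (eight) expand.grid(di = -1:1, dj = -1:1)
            else data.frame(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
    for (s in which(m == 1L)) {
      if (lab[s] != 0L) next
      nl <- nl + 1L
      queue <- s
      while (length(queue)) {
        q <- queue[[1]]; queue <- queue[-1]
        if (lab[q] != 0L) next
        lab[q] <- nl
        i <- (q - 1L) %% nrow(m) + 1L; j <- (q - 1L) %/% nrow(m) + 1L
        for (k in seq_len(nrow(offs))) {
          ii <- i + offs$di[k]; jj <- j + offs$dj[k]
          if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m) &&
              m[ii, jj] == 1L && lab[ii, jj] == 0L)
            queue <- c(queue, (jj - 1L) * nrow(m) + ii)
        }
      }
    }
    nl
  }
  expect_equal(comp_count(skr), 1)
  # the hole survives: background inside is not 4-connected to the outside
  inv <- 1L - skr
  expect_gt(comp_count(inv, eight = FALSE), 1)
})

test_that("skeletonization matches the independent reference implementation", {
  skip_if_not(python_available(), "python/scikit-image oracle not available")
  masks <- lapply(1:50, function(s) make_blob_mask(seed = s))
  refs <- skimage_thin_batch(masks)
  exact <- sum(mapply(function(m, r) identical(skeletonize_mask(m), r),
                      masks, refs))
  expect_equal(exact, 50L)  # pixel-exact agreement on every blob
})

test_that("grid overlay hits exactly the k*spacing lines", {
  g <- matrix(0, 200, 200)
  out <- overlay_grid(g, 80)
  lines_r <- which(apply(out == 255, 1, all))
  lines_c <- which(apply(out == 255, 2, all))
  expect_equal(lines_r, c(81, 161))  # 0-based rows 80, 160
  expect_equal(lines_c, c(81, 161))
  expect_equal(sum(out != 0), 200 * 4 - 4)

  # spacing larger than the raster leaves it unchanged
  expect_identical(overlay_grid(g, 500), g)
  # all-white input is unchanged
  w <- matrix(255, 90, 90)
  expect_identical(overlay_grid(w, 40), w)
  expect_error(overlay_grid(g, 1), "spacing")

  thick <- overlay_grid(matrix(0, 100, 100), 40, thickness = 2)
  expect_true(all(thick[41:42, ] == 255))
})

test_that("equalization reproduces closed-form mappings and monotonicity", {
  expect_true(all(equalize_hist(matrix(7L, 10, 10)) == 255))
  two <- matrix(c(rep(0L, 50), rep(255L, 50)), 10, 10)
  eq <- equalize_hist(two)
  expect_equal(sort(unique(as.vector(eq))), c(127, 255))
  expect_equal(eq[two == 0][1], 127)

  set.seed(15)
  f <- matrix(sample(0:255, 400, TRUE), 20, 20)
  g <- equalize_hist(f)
  # monotone: i <= j implies T(i) <= T(j)
  m <- tapply(as.vector(g), as.vector(f), unique)
  expect_true(all(diff(unlist(m)) >= 0))
  expect_error(equalize_hist(matrix(-1, 2, 2)), "intensities")
  expect_error(equalize_hist(matrix(300, 2, 2)), "intensities")

  # near-uniform output CDF for continuous-like input
  big <- matrix(sample(0:255, 256 * 40, TRUE), 256, 40)
  eqb <- equalize_hist(big)
  cdf <- cumsum(tabulate(eqb + 1L, 256)) / length(eqb)
  uniform <- (seq_len(256)) / 256
  expect_lt(max(abs(cdf - uniform)), 1 / 256 + 0.02)
})

test_that("compose_reference follows grid -> mask -> skeleton -> equalize", {
  cfg_irt <- modality_config("irt", grid_spacing = 10L)
  mask <- matrix(0L, 40, 40)
  mask[10:30, 10:30] <- 1L
  gray <- matrix(0, 40, 40)
  ref <- compose_reference(gray, mask, cfg_irt)
  sk <- skeletonize_mask(mask)
  # zero gray + full mask: only grid-within-mask and skeleton pixels at 255
  grid_in <- overlay_grid(gray, 10) * mask
  expected <- pmax(grid_in, sk * 255)
  expect_identical(unname(ref$image), unname(expected))
  # everything outside the mask is exactly 0
  expect_true(all(ref$image[mask == 0] == 0))
  expect_true(all(sk <= mask))

  # rgb config equalizes, irt config does not
  set.seed(16)
  gray2 <- matrix(sample(0:200, 1600, TRUE), 40, 40)
  cfg_rgb <- modality_config("rgb", grid_spacing = 10L)
  r_rgb <- compose_reference(gray2, mask, cfg_rgb)
  step3 <- overlay_grid(gray2, 10) * mask
  step3[sk == 1L] <- 255
  expect_identical(unname(compose_reference(gray2, mask, cfg_irt)$image),
                   unname(step3 * 1))
  expect_identical(unname(r_rgb$image), unname(equalize_hist(round(step3))))

  expect_error(compose_reference(gray, matrix(0L, 40, 40), cfg_irt), "empty mask")
  expect_error(compose_reference(gray, matrix(1L, 10, 10), cfg_irt), "shapes")
})

test_that("modality defaults differ exactly in grid, equalization and M", {
  rgb <- modality_config("rgb")
  irt <- modality_config("irt")
  expect_equal(rgb$grid_spacing, 80)
  expect_equal(irt$grid_spacing, 40)
  expect_true(rgb$equalize)
  expect_false(irt$equalize)
  expect_equal(rgb$magnitude_threshold, 100)
  expect_equal(irt$magnitude_threshold, 450)
  expect_equal(rgb$n_max, 90)
  expect_equal(rgb$min_distance, 10)
  expect_equal(rgb$T_steps, 30)
  expect_equal(rgb$peak_threshold, 3)
  expect_equal(rgb$detection_threshold, 0.7)
  expect_equal(sort(irt$rotations), c(-90, 0, 90))
  expect_error(modality_config("rgb", nonsense = 1), "unknown")
  over <- modality_config("irt", magnitude_threshold = 40)
  expect_equal(over$magnitude_threshold, 40)
})
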
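MOVEMENTS <- c("no_movement", "head", "one_arm", "both_arms",
               "one_leg", "both_legs", "slight")
POSTURES <- c("sitting", "laying")
ANGLES <- c(0, 45, 90)

#' Specify a synthetic scene
#'
#' Describes one simulated 30-second recording of a single person: posture,
#' in-plane angle of the body's longitudinal axis, movement class, imaging
#' modality, and nuisance effects (clothing flutter, sudden illumination
#' change). The defaults mirror the experimental protocol the simulator
#' emulates: seven movement classes, two postures, three angles, 30 s
#' clips. Rendering is a pure function of the spec (seed included).
#'
#' @param subject_id integer subject identifier (also perturbs the seed).
#' @param posture `"sitting"` or `"laying"`.
#' @param angle_deg body-axis angle: 0, 45 or 90 degrees.
#' @param movement one of `"no_movement"`, `"head"`, `"one_arm"`,
#'   `"both_arms"`, `"one_leg"`, `"both_legs"`, `"slight"`.
#' @param modality `"rgb"` (high-contrast, 3-channel) or `"irt"`
#'   (low-contrast, single-channel).
#' @param resolution `c(height, width)` in pixels.
#' @param duration_s clip length in seconds (> 0).
#' @param sample_rate_hz frames per second (> 0).
#' @param amplitude_px peak displacement of the moving limb's centroid, in
#'   pixels; default 0 for `no_movement`, 3 for `slight`, 150 otherwise.
#' @param movement_period_s period of the sinusoidal limb oscillation; at
#'   the 4 s default every 1 s signal step displaces the limb by exactly
#'   its amplitude.
#' @param nuisance list with `flutter_px` (boundary jitter amplitude) and
#'   `illumination_step` (global intensity offset applied from a random
#'   frame onward).
#' @param seed integer; one seeded generator drives all clip randomness.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(subject_id = 1L,
                       posture = c("sitting", "laying"),
                       angle_deg = 0,
                       movement = MOVEMENTS,
                       modality = c("rgb", "irt"),
                       resolution = c(400L, 520L),
                       duration_s = 30,
                       sample_rate_hz = 10,
                       amplitude_px = NULL,
                       movement_period_s = 4,
                       nuisance = list(flutter_px = 0, illumination_step = 0),
                       seed = 17L) {
  posture <- match.arg(posture)
  movement <- match.arg(movement)
  modality <- match.arg(modality)
  if (!angle_deg %in% ANGLES) stopf("angle_deg must be one of 0, 45, 90")
  if (duration_s <= 0) stopf("duration_s must be > 0")
  if (sample_rate_hz <= 0) stopf("sample_rate_hz must be > 0")
  amplitude_px <- amplitude_px %||%
    switch(movement, no_movement = 0, slight = 3, 150)
  if (amplitude_px < 0) stopf("amplitude_px must be >= 0")
  if (movement == "no_movement" && amplitude_px != 0)
    stopf("movement 'no_movement' requires amplitude_px = 0")
  nuisance <- modifyList(list(flutter_px = 0, illumination_step = 0), nuisance)
  structure(list(subject_id = as.integer(subject_id), posture = posture,
                 angle_deg = angle_deg, movement = movement,
                 modality = modality, resolution = as.integer(resolution),
                 duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 amplitude_px = amplitude_px,
                 movement_period_s = movement_period_s,
                 nuisance = nuisance, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Enumerate a study manifest
#'
#' Builds the cartesian study design: one clip per subject x posture x
#' movement x angle, with the ground-truth label assigned from the movement
#' class (`nonmoving` iff `no_movement`). With 20 subjects, 2 postures and
#' 7 movements this yields 280 clips per angle, 40 of them nonmoving.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param postures,movements,angles nonempty subsets of the protocol sets.
#' @param modality `"rgb"` or `"irt"`.
#' @param clip_dir prefix used to form `clip_path` entries.
#' @return a `data.frame` with columns `subject_id`, `posture`, `angle_deg`,
#'   `movement`, `modality`, `clip_path`, `label_truth`.
#' @export
make_manifest <- function(n_subjects, postures = POSTURES,
                          movements = MOVEMENTS, angles = ANGLES,
                          modality = c("rgb", "irt"), clip_dir = "clips") {
  modality <- match.arg(modality)
  if (length(n_subjects) != 1L || n_subjects < 1L)
    stopf("n_subjects must be a single integer >= 1")
  if (length(postures) == 0L || length(movements) == 0L || length(angles) == 0L)
    stopf("postures, movements and angles must all be nonempty")
  if (!all(postures %in% POSTURES)) stopf("unknown posture")
  if (!all(movements %in% MOVEMENTS)) stopf("unknown movement")
  if (!all(angles %in% ANGLES)) stopf("unknown angle")
  g <- expand.grid(movement = movements, posture = postures,
                   angle_deg = angles, subject_id = seq_len(n_subjects),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("subject_id", "posture", "angle_deg", "movement")]
  g$modality <- modality
  g$clip_path <- sprintf("%s/%s_s%03d_%s_a%02d_%s", clip_dir, modality,
                         g$subject_id, g$posture, g$angle_deg, g$movement)
  g$label_truth <- ifelse(g$movement == "no_movement", "nonmoving", "moving")
  rownames(g) <- NULL
  g
}

#' Build the scene spec for one manifest row
#'
#' @param manifest a manifest from [make_manifest()].
#' @param i row index.
#' @param base_seed study-level seed; each row gets a distinct derived seed.
#' @param ... overrides passed on to [scene_spec()] (e.g. `amplitude_px`,
#'   `nuisance`, `resolution`).
#' @return a [scene_spec()].
#' @export
manifest_spec <- function(manifest, i, base_seed = 17L, ...) {
  row <- manifest[i, ]
  scene_spec(subject_id = row$subject_id, posture = row$posture,
             angle_deg = row$angle_deg, movement = row$movement,
             modality = row$modality,
             seed = as.integer(base_seed) + 97L * i,
             ...)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> subject %d, %s, %d deg, %s, %s, %dx%d, %gs @ %g Hz, A=%g px\n",
              x$subject_id, x$posture, x$angle_deg, x$movement, x$modality,
              x$resolution[1], x$resolution[2], x$duration_s,
              x$sample_rate_hz, x$amplitude_px))
  invisible(x)
}

# ---- articulated silhouette geometry ------------------------------------

# parts: oriented rectangles (center, axis angle, half-length, half-width)
# or discs, in figure coordinates. z-order: later entries painted on top.
figure_parts <- function(posture) {
  if (posture == "laying") {
    list(
      leg_far  = list(type = "rect", c = c(105, -12), ang = 0, hl = 45, hw = 8,  base = 145),
      leg_near = list(type = "rect", c = c(105, 12),  ang = 0, hl = 45, hw = 8,  base = 140),
      arm_far  = list(type = "rect", c = c(-15, -30), ang = 0, hl = 35, hw = 7,  base = 135),
      arm_near = list(type = "rect", c = c(-15, 30),  ang = 0, hl = 35, hw = 7,  base = 130),
      torso    = list(type = "rect", c = c(0, 0),     ang = 0, hl = 60, hw = 22, base = 150),
      head     = list(type = "disc", c = c(-78, 0),   r = 20,             base = 170)
    )
  } else {
    list(
      leg_far  = list(type = "rect", c = c(40, 22), ang = 0, hl = 45, hw = 7,  base = 145),
      leg_near = list(type = "rect", c = c(40, 8),  ang = 0, hl = 45, hw = 7,  base = 140),
      arm_far  = list(type = "rect", c = c(-28, -35), ang = 90, hl = 35, hw = 7, base = 135),
      arm_near = list(type = "rect", c = c(28, -35),  ang = 90, hl = 35, hw = 7, base = 130),
      torso    = list(type = "rect", c = c(0, -30), ang = 90, hl = 50, hw = 22, base = 150),
      head     = list(type = "disc", c = c(0, -98), r = 20,            base = 170)
    )
  }
}

moving_parts <- function(movement) {
  switch(movement,
         no_movement = character(0),
         head = "head",
         one_arm = "arm_near",
         both_arms = c("arm_near", "arm_far"),
         one_leg = "leg_near",
         both_legs = c("leg_near", "leg_far"),
         slight = "arm_near")
}

rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

# pixel membership + part-local coordinates; cy/cx are 1-based image coords
part_pixels <- function(part, center, ang_deg, h, w) {
  cx <- center[1L]; cy <- center[2L]
  span <- function(lo, hi, n) {
    a <- max(1L, as.integer(floor(lo))); b <- min(n, as.integer(ceiling(hi)))
    if (a > b) integer(0L) else a:b
  }
  if (part$type == "disc") {
    r <- part$r
    ys <- span(cy - r, cy + r, h)
    xs <- span(cx - r, cx + r, w)
    if (length(ys) == 0L || length(xs) == 0L) return(NULL)
    yy <- rep(ys, times = length(xs)); xx <- rep(xs, each = length(ys))
    u <- xx - cx; v <- yy - cy
    keep <- u * u + v * v <= r * r
    list(y = yy[keep], x = xx[keep], u = u[keep], v = v[keep])
  } else {
    R <- rot2(ang_deg)
    ext <- abs(R %*% c(part$hl, 0)) + abs(R %*% c(0, part$hw))
    ys <- span(cy - ext[2L], cy + ext[2L], h)
    xs <- span(cx - ext[1L], cx + ext[1L], w)
    if (length(ys) == 0L || length(xs) == 0L) return(NULL)
    yy <- rep(ys, times = length(xs)); xx <- rep(xs, each = length(ys))
    dx <- xx - cx; dy <- yy - cy
    # project into part frame
    u <- R[1L, 1L] * dx + R[2L, 1L] * dy
    v <- R[1L, 2L] * dx + R[2L, 2L] * dy
    keep <- abs(u) <= part$hl & abs(v) <= part$hw
    list(y = yy[keep], x = xx[keep], u = u[keep], v = v[keep])
  }
}

#' Render a synthetic clip
#'
#' Renders the articulated silhouette (torso, head, two arms, two legs as
#' filled rectangles/discs) for the requested posture and body angle, with
#' the designated limb(s) oscillating as a rigid sinusoidal translation
#' whose centroid peak displacement equals `amplitude_px` (cosine phase, so
#' motion starts at zero velocity). RGB-like rendering uses high-contrast
#' within-body texture; IRT-like rendering uses a low-contrast single
#' channel with Gaussian sensor noise. Ground-truth masks share the
#' renderer's geometry exactly. Deterministic given the spec (bit-identical
#' re-renders).
#'
#' @param spec a [scene_spec()].
#' @param gray_only if `TRUE`, RGB scenes are rendered directly as their
#'   single-channel luminance (the form the pipeline consumes); saves
#'   memory on study-scale runs.
#' @return an object of class `rendered_clip`: list with `frames`
#'   ([frame_sequence]), `truth_masks` (one binary matrix per frame),
#'   `label_truth` (`"moving"`/`"nonmoving"`) and `spec`.
#' @export
render_clip <- function(spec, gray_only = FALSE) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$resolution[1L]; w <- spec$resolution[2L]
  parts <- figure_parts(spec$posture)
  R <- rot2(spec$angle_deg)
  # figure must fit the frame (plus room to move, for moving classes)
  if (h < 170 || w < 220)
    stopf("resolution %dx%d too small to contain the silhouette", h, w)
  movers <- moving_parts(spec$movement)
  n_frames <- as.integer(round(spec$duration_s * spec$sample_rate_hz)) + 1L
  dt <- 1 / spec$sample_rate_hz
  irt <- spec$modality == "irt"

  cx0 <- w / 2; cy0 <- h / 2
  # texture wavelengths per part (deterministic)
  lam <- list(torso = c(13, 17), head = c(11, 11), arm_near = c(9, 12),
              arm_far = c(9, 14), leg_near = c(12, 9), leg_far = c(14, 9))
  tex_amp <- if (irt) 8 else 45
  bg_base <- if (irt) 128 else 70

  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  background <- matrix(bg_base, h, w) + (if (irt) 0 else
    15 * sin(2 * pi * xx / 97) * sin(2 * pi * yy / 83))

  # each part moves perpendicular to its own long axis (figure coords,
  # rotated with the figure) so limbs never sweep behind the torso or out
  # of the frame
  part_dir <- function(nm) {
    d <- if (spec$posture == "laying") c(0, 1)
    else if (nm %in% c("leg_near", "leg_far")) c(0, 1)
    else c(1, 0)
    as.vector(R %*% d)
  }
  # moving parts are painted last so a swinging limb stays in front
  paint_order <- c(setdiff(names(parts), movers), movers)

  frames <- vector("list", n_frames)
  masks <- vector("list", n_frames)
  clip <- with_seed(spec$seed, {
    for (f in seq_len(n_frames)) {
      t <- (f - 1L) * dt
      img <- background
      msk <- matrix(0L, h, w)
      for (nm in paint_order) {
        p <- parts[[nm]]
        cen <- as.vector(R %*% p$c) + c(cx0, cy0)
        ang <- (if (p$type == "rect") p$ang else 0) + spec$angle_deg
        if (nm %in% movers && spec$amplitude_px > 0) {
          off <- spec$amplitude_px *
            cos(2 * pi * t / spec$movement_period_s)
          cen <- cen + off * part_dir(nm)
        }
        px <- part_pixels(p, cen, ang, h, w)
        if (is.null(px) || length(px$y) == 0L) next
        l <- lam[[nm]] %||% c(11, 13)
        val <- (if (irt) 178 else p$base) +
          tex_amp * sin(2 * pi * px$u / l[1L]) * sin(2 * pi * px$v / l[2L])
        idx <- cbind(px$y, px$x)
        img[idx] <- val
        msk[idx] <- 1L
      }
      if (irt) {
        img <- img + rnorm(h * w, 0, 0.02 * 255)
      } else {
        img <- img + runif(h * w, -3, 3)
      }
      img <- round(clamp(img, 0, 255))
      storage.mode(img) <- "integer"  # halves clip memory at study scale
      frames[[f]] <- img
      masks[[f]] <- msk
    }
    if (!irt && !gray_only) {
      frames <- lapply(frames, function(g) {
        a <- array(0, dim = c(h, w, 3L))
        a[, , 1L] <- clamp(round(g * 1.05), 0, 255)
        a[, , 2L] <- g
        a[, , 3L] <- clamp(round(g * 0.92), 0, 255)
        a
      })
    }
    fs <- frame_sequence(frames, timebase = dt, modality = spec$modality,
                         bitdepth = 8L)
    structure(list(frames = fs, truth_masks = masks,
                   label_truth = if (spec$movement == "no_movement")
                     "nonmoving" else "moving",
                   spec = spec),
              class = "rendered_clip")
  })
  if (spec$nuisance$flutter_px > 0 || spec$nuisance$illumination_step != 0) {
    clip <- add_nuisance(clip, spec$nuisance$flutter_px,
                         spec$nuisance$illumination_step)
  }
  clip
}

#' @export
print.rendered_clip <- function(x, ...) {
  cat(sprintf("<rendered_clip> %d frames, truth label '%s'\n",
              length(x$frames$frames), x$label_truth))
  print(x$spec)
  invisible(x)
}

#' Inject nuisance effects into a rendered clip
#'
#' `flutter_px` re-samples a 2-pixel band along the silhouette boundary at
#' a random sub-pixel offset per frame, emulating clothing flutter in wind;
#' `illumination_step` adds a global intensity offset from a random frame
#' onward, emulating a sudden sunlight change. The ground-truth label and
#' masks are unchanged. Offsets that leave the intensity range are clipped
#' with a warning.
#'
#' @param clip a [render_clip()] result.
#' @param flutter_px boundary jitter amplitude in pixels (>= 0).
#' @param illumination_step additive intensity offset.
#' @return the modified `rendered_clip`.
#' @export
add_nuisance <- function(clip, flutter_px = 0, illumination_step = 0) {
  stopifnot(inherits(clip, "rendered_clip"))
  if (flutter_px == 0 && illumination_step == 0) return(clip)
  fs <- clip$frames
  n <- length(fs$frames)
  gray <- frame_channels(fs$frames[[1L]]) == 1L
  clipped <- FALSE
  with_seed(clip$spec$seed + 104729L, {
    if (flutter_px > 0) {
      se <- matrix(1, 3, 3)
      for (f in seq_len(n)) {
        msk <- clip$truth_masks[[f]]
        band <- msk - binary_erode(binary_erode(msk, se), se)
        idx <- which(band == 1L)
        if (length(idx) == 0L) next
        dy <- runif(1, -flutter_px, flutter_px)
        dx <- runif(1, -flutter_px, flutter_px)
        h <- nrow(msk); w <- ncol(msk)
        iy <- clamp(((idx - 1L) %% h) + 1L + dy, 1, h - 1)
        ix <- clamp(((idx - 1L) %/% h) + 1L + dx, 1, w - 1)
        sample_plane <- function(m) {
          y0 <- floor(iy); x0 <- floor(ix); fy <- iy - y0; fx <- ix - x0
          (1 - fy) * ((1 - fx) * m[cbind(y0, x0)] + fx * m[cbind(y0, x0 + 1)]) +
            fy * ((1 - fx) * m[cbind(y0 + 1, x0)] + fx * m[cbind(y0 + 1, x0 + 1)])
        }
        if (gray) {
          fr <- fs$frames[[f]]
          fr[idx] <- round(sample_plane(fr))
          fs$frames[[f]] <- fr
        } else {
          fr <- fs$frames[[f]]
          for (ch in 1:3) {
            plane <- fr[, , ch]
            plane[idx] <- round(sample_plane(plane))
            fr[, , ch] <- plane
          }
          fs$frames[[f]] <- fr
        }
      }
    }
    if (illumination_step != 0) {
      k <- sample.int(n - 1L, 1L) + 1L  # step frame: 2..n
      for (f in k:n) {
        fr <- fs$frames[[f]] + illumination_step
        if (any(fr < 0 | fr > 255)) clipped <- TRUE
        fs$frames[[f]] <- clamp(fr, 0, 255)
      }
    }
  })
  if (clipped)
    warnf("illumination step clipped intensities to [0, 255]")
  clip$frames <- fs
  clip
}

#' Write / read a rendered clip as a frame directory
#'
#' Frames go to PNG (8-bit), truth masks to 1-bit-content PNGs under
#' `masks/`, and an `index.json` records the spec, seed and truth label.
#'
#' @param clip a `rendered_clip`.
#' @param path output directory.
#' @return `path` invisibly (`write_clip`); a `rendered_clip` (`read_clip`).
#' @export
write_clip <- function(clip, path) {
  stopifnot(inherits(clip, "rendered_clip"))
  write_frames(clip$frames, path)
  mdir <- file.path(path, "masks")
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  n <- length(clip$truth_masks)
  fmt <- sprintf("mask_%%0%dd.png", max(4L, nchar(n)))
  for (i in seq_len(n)) {
    png::writePNG(clip$truth_masks[[i]] * 1.0,
                  file.path(mdir, sprintf(fmt, i - 1L)))
  }
  spec <- clip$spec
  jsonlite::write_json(
    list(timebase = clip$frames$timebase, modality = spec$modality,
         n_frames = length(clip$frames$frames),
         label_truth = clip$label_truth, spec = unclass(spec)),
    file.path(path, "index.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_clip
#' @param path clip directory written by [write_clip()].
#' @export
read_clip <- function(path) {
  idx <- jsonlite::read_json(file.path(path, "index.json"))
  fs <- read_frames(path)
  mdir <- file.path(path, "masks")
  mfiles <- sort(list.files(mdir, pattern = "\\.png$", full.names = TRUE))
  masks <- lapply(mfiles, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    (m > 0.5) * 1L
  })
  sp <- idx$spec
  spec <- scene_spec(subject_id = sp$subject_id, posture = sp$posture,
                     angle_deg = sp$angle_deg, movement = sp$movement,
                     modality = sp$modality,
                     resolution = unlist(sp$resolution),
                     duration_s = sp$duration_s,
                     sample_rate_hz = sp$sample_rate_hz,
                     amplitude_px = sp$amplitude_px,
                     movement_period_s = sp$movement_period_s,
                     nuisance = lapply(sp$nuisance, unlist),
                     seed = sp$seed)
  structure(list(frames = fs, truth_masks = masks,
                 label_truth = idx$label_truth, spec = spec),
            class = "rendered_clip")
}

#' Write / read a study manifest as CSV
#'
#' @param manifest a manifest `data.frame` from [make_manifest()].
#' @param path CSV file path.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
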
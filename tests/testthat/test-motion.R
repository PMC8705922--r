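# movement signal extraction and clip classification

# a track_set with prescribed per-step displacement magnitudes for one point
# per listed magnitude, over T steps at 1 frame/second (dt = 1)
synthetic_tracks <- function(mags_by_point, T_steps) {
  n <- length(mags_by_point)
  traj <- array(0, dim = c(T_steps + 1, n, 2))
  status <- matrix(TRUE, T_steps + 1, n)
  for (p in seq_len(n)) {
    mags <- rep_len(mags_by_point[[p]], T_steps)
    traj[, p, 1] <- cumsum(c(0, mags))  # move along x only
  }
  structure(list(pts = traj[1, , , drop = TRUE], scores = rep(1, n),
                 traj = traj, status = status, timebase = 1),
            class = "track_set")
}

test_that("relevant counts threshold strictly at M", {
  # three points with step magnitudes 120, 80, 101 at every instant
  tr <- synthetic_tracks(list(120, 80, 101), T_steps = 5)
  sig <- movement_signal(tr, M = 100, T_steps = 5)
  expect_equal(sig$f, rep(2L, 5))

  # magnitude exactly M is excluded (strict inequality)
  tr2 <- synthetic_tracks(list(100), T_steps = 4)
  expect_equal(movement_signal(tr2, M = 100, T_steps = 4)$f, rep(0L, 4))
  tr3 <- synthetic_tracks(list(100 + 1e-9), T_steps = 4)
  expect_equal(movement_signal(tr3, M = 100, T_steps = 4)$f, rep(1L, 4))

  # all-zero magnitudes give the zero signal
  tr0 <- synthetic_tracks(list(0, 0), T_steps = 6)
  expect_equal(movement_signal(tr0, M = 100, T_steps = 6)$f, rep(0L, 6))
})

test_that("invalid points are excluded and empty tracks warn", {
  tr <- synthetic_tracks(list(150, 150), T_steps = 4)
  tr$status[3:5, 2] <- FALSE  # second point dies after step 2
  sig <- movement_signal(tr, M = 100, T_steps = 4)
  expect_equal(sig$f, c(2L, 1L, 1L, 1L))

  tr$status[, ] <- FALSE
  expect_warning(sig0 <- movement_signal(tr, M = 100, T_steps = 4),
                 "no valid")
  expect_equal(sig0$f, rep(0L, 4))
})

test_that("classification applies the th = 3 peak rule", {
  mk <- function(active) {
    f <- integer(30)
    if (active > 0) f[seq_len(active)] <- 5L
    structure(list(f = f, T = 30L, M = 100, active_steps = sum(f > 0),
                   n_points = 10L), class = "movement_signal")
  }
  expect_equal(classify_signal(mk(0))$label_code, 1L)   # f == 0 -> nonmoving
  expect_equal(classify_signal(mk(2))$label_code, 1L)   # 2 active -> nonmoving
  expect_equal(classify_signal(mk(3))$label_code, 0L)   # 3 active -> moving
  expect_equal(classify_signal(mk(30))$label_code, 0L)
  # score decreases with activity
  expect_gt(classify_signal(mk(2))$score, classify_signal(mk(10))$score)
  expect_equal(classify_signal(mk(0))$score, 1)
})

test_that("classification is monotone in M and in th", {
  set.seed(30)
  mags <- lapply(1:8, function(i) runif(12, 0, 200))
  tr <- synthetic_tracks(mags, T_steps = 12)
  Ms <- c(20, 50, 100, 150, 250)
  acts <- vapply(Ms, function(M)
    movement_signal(tr, M = M, T_steps = 12)$active_steps, numeric(1))
  expect_true(all(diff(acts) <= 0))  # raising M never increases activity
  # raising M can only flip moving -> nonmoving
  labels <- vapply(Ms, function(M)
    classify_signal(movement_signal(tr, M = M, T_steps = 12))$label_code,
    integer(1))
  expect_true(all(diff(labels) >= 0))
  # raising th can only flip moving -> nonmoving
  sig <- movement_signal(tr, M = 100, T_steps = 12)
  lab_th <- vapply(1:12, function(th) classify_signal(sig, th)$label_code,
                   integer(1))
  expect_true(all(diff(lab_th) >= 0))
})

test_that("run_clip classifies static and moving synthetic clips end to end", {
  cfg <- modality_config("rgb")
  static <- render_clip(scene_spec(1, "laying", 0, "no_movement", seed = 31,
                                   resolution = c(260, 340), duration_s = 10,
                                   sample_rate_hz = 3), gray_only = TRUE)
  r <- run_clip(static$frames, truth_backend(static), cfg)
  expect_equal(r$label, "nonmoving")
  expect_equal(result_code(r), 1L)

  # amplitude 120 at period 4 s: every 1 s step displaces the limb by
  # ~120 px > M = 100
  moving <- render_clip(scene_spec(1, "laying", 0, "one_arm", seed = 32,
                                   resolution = c(340, 420), duration_s = 12,
                                   sample_rate_hz = 8, amplitude_px = 120,
                                   movement_period_s = 4), gray_only = TRUE)
  rm_ <- run_clip(moving$frames, truth_backend(moving), cfg)
  expect_equal(rm_$label, "moving")
  expect_equal(result_code(rm_), 0L)

  # determinism end to end
  r2 <- run_clip(moving$frames, truth_backend(moving), cfg)
  expect_identical(rm_$signal$f, r2$signal$f)
})

test_that("exactly two isolated motion bursts stay below the peak rule", {
  # limb moves during the first 2 seconds only (the remaining frames are
  # frozen at the last moving frame): two active instants < th = 3
  cfg <- modality_config("rgb", T_steps = 6L)
  sp <- scene_spec(1, "laying", 0, "one_arm", seed = 33, duration_s = 6,
                   sample_rate_hz = 10, amplitude_px = 150,
                   movement_period_s = 4)
  clip <- render_clip(sp, gray_only = TRUE)
  freeze_after <- function(clip, n_keep) {
    for (i in (n_keep + 1):length(clip$frames$frames)) {
      clip$frames$frames[[i]] <- clip$frames$frames[[n_keep]]
      clip$truth_masks[[i]] <- clip$truth_masks[[n_keep]]
    }
    clip
  }
  two <- freeze_after(clip, 21L)  # motion through t = 2 s only
  r2 <- run_clip(two$frames, truth_backend(two), cfg)
  expect_equal(r2$signal$active_steps, 2)
  expect_equal(r2$label, "nonmoving")
  # motion sustained through 4 s clears the threshold
  three <- freeze_after(clip, 41L)
  r3 <- run_clip(three$frames, truth_backend(three), cfg)
  expect_gte(r3$signal$active_steps, 3)
  expect_equal(r3$label, "moving")
})

test_that("undetermined outcomes carry a reason and map conservatively", {
  cfg <- modality_config("rgb")
  flat <- frame_sequence(list(matrix(128, 220, 280), matrix(128, 220, 280)),
                         timebase = 1, modality = "rgb")
  none <- stub_backend(list())
  r <- run_clip(flat, none, cfg)
  expect_equal(r$label, "undetermined")
  expect_match(r$reason, "no person")
  expect_equal(result_code(r), 1L)
  expect_equal(result_code(r, undetermined_as = 0L), 0L)

  # person found but featureless interior: insufficient features
  mask <- matrix(0L, 220, 280)
  mask[60:160, 60:220] <- 1L
  bk <- truth_backend(mask)
  flat_cfg <- modality_config("rgb", grid_spacing = 500L)  # no grid lines
  r2 <- run_clip(flat, bk, flat_cfg)
  expect_true(r2$label %in% c("undetermined", "nonmoving"))
})

test_that("clip results serialize to JSON", {
  sig <- structure(list(f = c(0L, 2L, 0L), T = 3L, M = 100,
                        active_steps = 1L, n_points = 4L),
                   class = "movement_signal")
  res <- classify_signal(sig)
  p <- tempfile(fileext = ".json")
  write_clip_result(res, p, config = modality_config("rgb"))
  back <- jsonlite::read_json(p)
  expect_equal(back$label, "nonmoving")
  expect_equal(unlist(back$f), c(0, 2, 0))
  expect_equal(back$config$magnitude_threshold, 100)
  unlink(p)
})
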
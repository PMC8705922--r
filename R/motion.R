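#' Extract the movement signal from tracked points
#'
#' The clip's tracked span is divided into `T` equal steps (default: one
#' per second of a 30 s clip). The displacement vector `u` of each point at
#' step t is its position change between the step boundaries, divided by
#' the step duration in seconds ("distance/dt", px/s); `f(t)` counts the
#' valid points whose magnitude strictly exceeds the relevant-motion
#' threshold `M`. For a clip sampled at 1 frame per second this is exactly
#' the per-frame displacement in pixels (dt = 1 s).
#'
#' @param tracks a tracked [track_points()] result.
#' @param M relevant-magnitude threshold in px/s (100 for visible, 450 for
#'   thermal configurations).
#' @param T_steps number of signal samples (default 30, one per second of
#'   a 30 s clip); capped at the number of tracked steps.
#' @return an object of class `movement_signal`: list with `f` (counts per
#'   instant), `T`, `M`, `active_steps` and `n_points`.
#' @export
movement_signal <- function(tracks, M, T_steps = 30L) {
  stopifnot(inherits(tracks, "track_set"))
  if (is.null(tracks$traj)) stopf("track_points() must be run first")
  K <- dim(tracks$traj)[1L] - 1L
  if (K < 1L) stopf("need at least one tracked step")
  T_steps <- min(as.integer(T_steps), K)
  n <- dim(tracks$traj)[2L]
  f <- integer(T_steps)
  any_valid <- FALSE
  bounds <- as.integer(round(seq_len(T_steps) * K / T_steps)) + 1L
  prev_b <- c(1L, bounds[-T_steps])
  for (t in seq_len(T_steps)) {
    if (n == 0L) next
    i1 <- prev_b[t]; i2 <- bounds[t]
    dt_s <- (i2 - i1) * tracks$timebase
    ok <- tracks$status[i2, ] & tracks$status[i1, ]
    if (!any(ok) || dt_s <= 0) next
    any_valid <- TRUE
    du <- (tracks$traj[i2, ok, 1L] - tracks$traj[i1, ok, 1L]) / dt_s
    dv <- (tracks$traj[i2, ok, 2L] - tracks$traj[i1, ok, 2L]) / dt_s
    f[t] <- sum(sqrt(du * du + dv * dv) > M)
  }
  if (!any_valid) warnf("no valid tracked points at any instant; f is identically 0")
  structure(list(f = f, T = T_steps, M = M,
                 active_steps = sum(f > 0L), n_points = n),
            class = "movement_signal")
}

#' @export
print.movement_signal <- function(x, ...) {
  cat(sprintf("<movement_signal> T=%d, M=%g, active steps %d, %d points\n",
              x$T, x$M, x$active_steps, x$n_points))
  invisible(x)
}

#' Classify a movement signal
#'
#' A clip is "moving" (label 0) when the movement-count signal is nonzero
#' at `th` or more instants, else "nonmoving" (label 1, the positive class:
#' the surrogate for potential unconsciousness). The continuous score for
#' precision-recall analysis is `1 - active_steps / T` (higher = more
#' likely nonmoving).
#'
#' @param signal a [movement_signal()].
#' @param th minimum number of active instants for "moving" (default 3).
#' @return an object of class `clip_result` with `label` ("moving" /
#'   "nonmoving"), `label_code` (0/1), `score` and the signal.
#' @export
classify_signal <- function(signal, th = 3L) {
  stopifnot(inherits(signal, "movement_signal"))
  moving <- signal$active_steps >= th
  structure(list(label = if (moving) "moving" else "nonmoving",
                 label_code = if (moving) 0L else 1L,
                 score = 1 - signal$active_steps / signal$T,
                 signal = signal, reason = NULL),
            class = "clip_result")
}

undetermined_result <- function(reason) {
  structure(list(label = "undetermined", label_code = NA_integer_,
                 score = NA_real_, signal = NULL, reason = reason),
            class = "clip_result")
}

#' @export
print.clip_result <- function(x, ...) {
  cat(sprintf("<clip_result> %s (code %s), score %s%s\n", x$label,
              x$label_code,
              if (is.na(x$score)) "NA" else sprintf("%.3f", x$score),
              if (is.null(x$reason)) "" else paste0(" [", x$reason, "]")))
  invisible(x)
}

#' Evaluation-compatible binary label
#'
#' Maps a clip result to the 0/1 labels used in evaluation; undetermined
#' results (insufficient features or no person found) are counted as the
#' positive class (nonmoving) by default, the conservative choice for
#' triage.
#'
#' @param result a [classify_signal()] result.
#' @param undetermined_as label to substitute for undetermined outcomes.
#' @return integer 0 (moving) or 1 (nonmoving).
#' @export
result_code <- function(result, undetermined_as = 1L) {
  if (is.na(result$label_code)) undetermined_as else result$label_code
}

#' Run the full detection pipeline on one clip
#'
#' The complete chain: the first frame is converted to grayscale and
#' preprocessed (person mask via the backend - with rotation merging for
#' thermal configurations - skeleton, white grid, optional equalization);
#' feature points are selected on the processed reference and tracked as
#' plain grayscale through the remaining frames; the movement signal is
#' extracted and classified. Deterministic for fixed inputs.
#'
#' @param frames a [frame_sequence] (>= 2 frames).
#' @param backend a segmentation backend (see [truth_backend()]).
#' @param config a [modality_config()].
#' @return a `clip_result`; "undetermined" (with a reason) when no person
#'   is found or no feature point can be selected.
#' @export
run_clip <- function(frames, backend, config) {
  stopifnot(inherits(frames, "frame_sequence"),
            inherits(config, "modality_config"))
  if (length(frames$frames) < 2L) stopf("a clip needs at least 2 frames")
  gray <- gray_sequence(frames)
  ref_frame <- matrix(as.numeric(gray$frames[[1L]]), nrow(gray$frames[[1L]]))
  mask <- tryCatch({
    if (length(config$rotations) > 1L)
      detect_with_rotations(ref_frame, backend, rotations = config$rotations,
                            threshold = config$detection_threshold)
    else
      detect_person(ref_frame, backend, threshold = config$detection_threshold)
  }, stillwatch_no_person = function(e) NULL)
  if (is.null(mask)) return(undetermined_result("no person found"))
  ref <- compose_reference(ref_frame, mask, config)
  tracks <- select_features(ref, n_max = config$n_max,
                            min_distance = config$min_distance,
                            border = (config$lk_window - 1L) / 2L + 2L)
  if (nrow(tracks$pts) == 0L)
    return(undetermined_result("insufficient features"))
  tracks <- track_points(tracks, gray, window = config$lk_window,
                         max_level = config$lk_max_level,
                         max_iter = config$lk_max_iter, eps = config$lk_eps)
  sig <- suppressWarnings(movement_signal(tracks, M = config$magnitude_threshold,
                                          T_steps = config$T_steps))
  classify_signal(sig, th = config$peak_threshold)
}

#' Serialize a clip result to JSON
#'
#' @param result a `clip_result`.
#' @param path output file.
#' @param config optional [modality_config()] to embed.
#' @export
write_clip_result <- function(result, path, config = NULL) {
  out <- list(label = result$label, label_code = result$label_code,
              score = result$score,
              f = if (!is.null(result$signal)) result$signal$f,
              T = if (!is.null(result$signal)) result$signal$T,
              M = if (!is.null(result$signal)) result$signal$M,
              reason = result$reason)
  if (!is.null(config)) out$config <- unclass(config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
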
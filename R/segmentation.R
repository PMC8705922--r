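#' Construct a body mask
#'
#' Binary raster of the detected person region, with the detection
#' confidence and the provenance of the mask.
#'
#' @param raster binary matrix (values 0/1), same shape as the frame.
#' @param score detection confidence in `[0, 1]`.
#' @param source `"detector"`, `"truth"` or `"merged"`.
#' @return an object of class `body_mask`.
#' @export
body_mask <- function(raster, score = 1, source = c("truth", "detector", "merged")) {
  source <- match.arg(source)
  if (!is_binary(raster)) stopf("mask raster must be a binary (0/1) matrix")
  if (score < 0 || score > 1) stopf("score must lie in [0, 1]")
  structure(list(raster = raster, score = score, source = source),
            class = "body_mask")
}

#' @export
print.body_mask <- function(x, ...) {
  cat(sprintf("<body_mask> %dx%d, %d foreground px, score %.2f, source %s\n",
              nrow(x$raster), ncol(x$raster), sum(x$raster), x$score, x$source))
  invisible(x)
}

#' Segmentation backends
#'
#' A segmentation backend is a function `frame -> list of detections`, each
#' detection a list with `mask` (binary matrix shaped like the frame),
#' `score` (confidence) and `class` (e.g. `"person"`). Any pretrained
#' instance-segmentation model can be adapted to this contract;
#' `truth_backend()` wraps known ground-truth masks (e.g. a synthetic
#' clip's), and `stub_backend()` builds fixed-response backends for tests.
#'
#' @param mask a binary matrix, a [body_mask], or a `rendered_clip` (whose
#'   first-frame truth mask is used).
#' @param score the confidence the backend reports.
#' @return a backend function.
#' @export
truth_backend <- function(mask, score = 1) {
  if (inherits(mask, "rendered_clip")) mask <- mask$truth_masks[[1L]]
  if (inherits(mask, "body_mask")) mask <- mask$raster
  force(score)
  function(frame) {
    if (!identical(dim(mask), dim(frame)[1:2]))
      return(list())
    list(list(mask = mask, score = score, class = "person"))
  }
}

#' @rdname truth_backend
#' @param detections list of detections returned for every frame.
#' @export
stub_backend <- function(detections) {
  force(detections)
  function(frame) detections
}

#' Detect the person mask in a frame
#'
#' Runs the backend and returns the highest-scoring `"person"` detection at
#' or above the confidence threshold. Backends that expect 3-channel input
#' (attribute `channels = 3`) receive the gray plane replicated to three
#' channels, the strategy used for thermal frames.
#'
#' @param frame single-channel numeric matrix.
#' @param backend a segmentation backend (see [truth_backend()]).
#' @param threshold detection confidence threshold (default 0.7; proposals
#'   below it are ignored).
#' @return a [body_mask] with `source = "detector"` (score as reported), or
#'   an error of class `stillwatch_no_person` when no detection qualifies.
#' @export
detect_person <- function(frame, backend, threshold = 0.7) {
  if (length(frame) == 0L) stopf("frame is empty")
  input <- frame
  if (identical(attr(backend, "channels"), 3L) && length(dim(frame)) == 2L) {
    input <- array(rep(frame, 3L), dim = c(dim(frame), 3L))
  }
  dets <- backend(input)
  keep <- Filter(function(d) identical(d$class, "person") &&
                   d$score >= threshold, dets)
  if (length(keep) == 0L) {
    stop(structure(class = c("stillwatch_no_person", "error", "condition"),
                   list(message = "no person found at or above the detection threshold",
                        call = sys.call(-1L))))
  }
  scores <- vapply(keep, function(d) d$score, numeric(1L))
  best <- keep[[which.max(scores)]]  # ties: first in backend order
  if (!identical(dim(best$mask), dim(frame)[1:2]))
    stopf("backend mask shape does not match the frame")
  body_mask((best$mask != 0) * 1L, score = best$score, source = "detector")
}

#' Detect with rotation merging
#'
#' The rotation-merge strategy for weak (thermal) detections: the frame is
#' rotated exactly by each multiple of 90 degrees, [detect_person()] is run
#' per rotation where it succeeds, each mask is inverse-rotated, and the
#' pixelwise union is returned (`source = "merged"`, score = max over
#' contributing rotations). Succeeds if at least one rotation succeeds.
#'
#' @inheritParams detect_person
#' @param rotations integer degrees, multiples of 90 (default 0, +90, -90).
#' @return a [body_mask] with `source = "merged"`.
#' @export
detect_with_rotations <- function(frame, backend, rotations = c(0, 90, -90),
                                  threshold = 0.7) {
  if (any(rotations %% 90 != 0)) stopf("rotations must be multiples of 90 degrees")
  merged <- NULL; best_score <- 0
  for (r in rotations) {
    k <- as.integer(r / 90)
    rot <- rot90_mat(frame, k)
    bm <- tryCatch(detect_person(rot, backend, threshold),
                   stillwatch_no_person = function(e) NULL)
    if (is.null(bm)) next
    back <- rot90_mat(bm$raster, -k)
    merged <- if (is.null(merged)) back else pmax(merged, back)
    best_score <- max(best_score, bm$score)
  }
  if (is.null(merged)) {
    stop(structure(class = c("stillwatch_no_person", "error", "condition"),
                   list(message = "no person found in any rotation",
                        call = sys.call(-1L))))
  }
  body_mask(merged, score = best_score, source = "merged")
}
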
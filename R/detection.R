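# Detector contract, detection schedule, and ROI source selection.
#
# The nostril detector (a trained single-shot model on the real device) runs
# only on scheduled frames (every `stride`-th frame, default every second
# frame) to halve its cost; a Kalman tracker supplies the ROI everywhere
# else. The detector itself is pluggable: any function taking a temperature
# map and returning a detection (or NULL) fits the contract. For hermetic
# testing, an oracle detector perturbs the ground-truth ROI of synthetic
# scenes.

#' Construct a detection (bounding box with confidence)
#'
#' @param x1,y1 Top-left corner in pixels (0-based).
#' @param x2,y2 Bottom-right corner in pixels; `x2 >= x1`, `y2 >= y1`.
#' @param confidence Detector confidence in \code{[0, 1]}.
#' @return A named list of class `detection`.
#' @export
detection <- function(x1, y1, x2, y2, confidence = 1) {
  if (x2 < x1 || y2 < y1) {
    stop("invalid box: corners are inverted", call. = FALSE)
  }
  stopifnot(confidence >= 0, confidence <= 1)
  structure(
    list(x1 = x1, y1 = y1, x2 = x2, y2 = y2, confidence = confidence),
    class = "detection"
  )
}

#' Is frame `k` on the detection schedule?
#'
#' The detector runs on frames with `k mod stride == 0`, so with the default
#' stride of 2 it runs on even frames only, halving the detection rate
#' relative to the camera rate.
#'
#' @param k Frame index (0-based, >= 0). Vectorized.
#' @param stride Detection stride (integer >= 1, default 2).
#' @return Logical vector.
#' @export
is_detection_frame <- function(k, stride = 2L) {
  stopifnot(all(k >= 0), stride >= 1)
  k %% stride == 0
}

#' Select the ROI source for a frame
#'
#' Uses the detector's box on scheduled frames when a detection exists, and
#' the tracker's prediction otherwise.
#'
#' @param k Frame index (0-based).
#' @param det A [detection()] or `NULL` if the detector produced nothing (or
#'   was not run).
#' @param predicted Numeric ROI `c(x1, y1, x2, y2)` from the tracker, or
#'   `NULL` if the track is not initialized.
#' @param stride Detection stride.
#' @return A list with `roi` (numeric `c(x1, y1, x2, y2)`) and `source`
#'   (`"detector"` or `"tracker"`), or `NULL` when neither source is
#'   available (the pipeline skips the sample).
#' @export
select_roi <- function(k, det = NULL, predicted = NULL, stride = 2L) {
  if (is_detection_frame(k, stride) && !is.null(det)) {
    return(list(roi = c(det$x1, det$y1, det$x2, det$y2), source = "detector"))
  }
  if (!is.null(predicted)) {
    return(list(roi = as.numeric(predicted), source = "tracker"))
  }
  NULL
}

#' Keep the best of several detections
#'
#' The pipeline tracks a single nostril box; when a detector yields several,
#' the highest-confidence one wins. Detections below `confidence_min` are
#' discarded.
#'
#' @param dets A list of [detection()] objects (possibly empty).
#' @param confidence_min Minimum confidence to accept (default 0.25).
#' @return A single [detection()] or `NULL`.
#' @export
filter_detections <- function(dets, confidence_min = 0.25) {
  if (length(dets) == 0) return(NULL)
  conf <- vapply(dets, function(d) d$confidence, numeric(1))
  keep <- conf >= confidence_min
  if (!any(keep)) return(NULL)
  dets[keep][[which.max(conf[keep])]]
}

#' Oracle detector for synthetic scenes
#'
#' A hermetic stand-in for the trained nostril detector: returns the
#' ground-truth ROI perturbed by independent uniform corner jitter, clipped to
#' the frame, and simulates missed detections with probability `miss_rate`.
#' Deterministic for a fixed `seed`; with `seed = NULL` it consumes the
#' session RNG stream.
#'
#' @param truth_roi Numeric `c(x1, y1, x2, y2)` ground-truth box.
#' @param frame_w,frame_h Frame dimensions in pixels, used for clipping.
#' @param jitter_px Maximum absolute uniform jitter per corner coordinate.
#' @param miss_rate Probability of returning no detection (`0 <= miss_rate < 1`).
#' @param seed Optional integer seed for reproducible jitter/misses.
#' @return A [detection()] or `NULL` (missed).
#' @export
oracle_detector <- function(truth_roi, frame_w, frame_h, jitter_px = 0,
                            miss_rate = 0, seed = NULL) {
  stopifnot(miss_rate >= 0, miss_rate < 1, length(truth_roi) == 4)
  draw <- function() {
    if (miss_rate > 0 && stats::runif(1) < miss_rate) return(NULL)
    jit <- if (jitter_px > 0) stats::runif(4, -jitter_px, jitter_px) else rep(0, 4)
    box <- truth_roi + jit
    x1 <- min(max(box[1], 0), frame_w - 1)
    x2 <- min(max(box[3], 0), frame_w - 1)
    y1 <- min(max(box[2], 0), frame_h - 1)
    y2 <- min(max(box[4], 0), frame_h - 1)
    detection(min(x1, x2), min(y1, y2), max(x1, x2), max(y1, y2), confidence = 1)
  }
  if (is.null(seed)) {
    draw()
  } else {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
    draw()
  }
}
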
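# Coldest-pixel nostril-temperature extraction and the sliding analysis
# buffer.
#
# Inhaled ambient air cools the nostril rim; exhaled air warms it. The
# per-frame minimum temperature inside the tracked ROI is therefore an
# airflow-related scalar signal. A sliding buffer of about 20 s keeps several
# respiratory cycles available to the phase detector while staying responsive.

#' Extract the minimum temperature within an ROI
#'
#' Real-valued ROI corners are rounded half-away-from-zero to integers, then
#' the inclusive pixel set `x1 <= x <= x2`, `y1 <= y <= y2` (0-based) is
#' scanned after clipping to the frame. Ties are broken row-major-first.
#'
#' @param map Numeric temperature matrix.
#' @param roi Numeric `c(x1, y1, x2, y2)` (0-based, possibly real-valued).
#' @param percentile Robust variant: when > 0, the given lower quantile of
#'   ROI temperatures is returned instead of the strict minimum (and `px`,
#'   `py` refer to the pixel attaining the nearest value). Default 0 (strict
#'   minimum, as the method prescribes).
#' @return A list with `t_min` (degrees C), `px`, `py` (0-based coordinates of
#'   the attaining pixel), `roi_area` (pixel count), or `NULL` when the
#'   clipped ROI is empty (no-sample condition).
#' @export
extract_min_temperature <- function(map, roi, percentile = 0) {
  stopifnot(length(roi) == 4)
  h <- nrow(map)
  w <- ncol(map)
  r <- round_half_away(roi)
  x1 <- max(r[1], 0); x2 <- min(r[3], w - 1)
  y1 <- max(r[2], 0); y2 <- min(r[4], h - 1)
  if (x1 > x2 || y1 > y2) return(NULL)
  sub <- unclass(map)[(y1 + 1):(y2 + 1), (x1 + 1):(x2 + 1), drop = FALSE]
  if (percentile > 0) {
    t_min <- as.numeric(stats::quantile(sub, percentile, names = FALSE))
    target <- which(abs(sub - t_min) == min(abs(sub - t_min)), arr.ind = TRUE)
  } else {
    t_min <- min(sub)
    target <- which(sub == t_min, arr.ind = TRUE)
  }
  target <- target[order(target[, 1], target[, 2]), , drop = FALSE]
  list(
    t_min = t_min,
    px = unname(x1 + target[1, 2] - 1L),
    py = unname(y1 + target[1, 1] - 1L),
    roi_area = length(sub)
  )
}

round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Create an empty breathing-signal buffer
#'
#' A sliding buffer holding the most recent ~20 s of coldest-pixel samples:
#' capacity `N = ceiling(20 * f_cam)` samples.
#'
#' @param f_cam Camera frame rate in Hz.
#' @param window_s Buffer span in seconds (default 20).
#' @return An object of class `breath_signal`: a tibble with columns
#'   `frame_index`, `time_s`, `t_min_c`, `px`, `py`, `roi_area` and
#'   attributes `f_cam` and `capacity`.
#' @export
breath_signal <- function(f_cam, window_s = 20) {
  stopifnot(f_cam > 0, window_s > 0)
  out <- tibble::tibble(
    frame_index = integer(), time_s = numeric(), t_min_c = numeric(),
    px = integer(), py = integer(), roi_area = numeric()
  )
  attr(out, "f_cam") <- f_cam
  attr(out, "capacity") <- as.integer(ceiling(window_s * f_cam))
  class(out) <- c("breath_signal", class(out))
  out
}

#' Append a sample to a breathing-signal buffer
#'
#' Frame indices must be strictly increasing; the oldest sample is evicted
#' once the buffer exceeds its ~20-s capacity.
#'
#' @param sig A [breath_signal()].
#' @param frame_index Frame index of the sample (0-based).
#' @param t_min_c Coldest-pixel temperature in degrees Celsius.
#' @param px,py Coordinates of the coldest pixel (0-based).
#' @param roi_area ROI area in pixels.
#' @return The updated `breath_signal`.
#' @export
push_sample <- function(sig, frame_index, t_min_c, px = NA_integer_,
                        py = NA_integer_, roi_area = NA_real_) {
  stopifnot(inherits(sig, "breath_signal"))
  f_cam <- attr(sig, "f_cam")
  capacity <- attr(sig, "capacity")
  n <- nrow(sig)
  if (n > 0 && frame_index <= sig$frame_index[n]) {
    stop(sprintf("ordering error: frame index %d is not after the last stored (%d)",
                 frame_index, sig$frame_index[n]), call. = FALSE)
  }
  row <- tibble::tibble(
    frame_index = as.integer(frame_index),
    time_s = frame_index / f_cam,
    t_min_c = t_min_c,
    px = as.integer(px), py = as.integer(py),
    roi_area = as.numeric(roi_area)
  )
  out <- dplyr::bind_rows(sig, row)
  if (nrow(out) > capacity) {
    out <- out[(nrow(out) - capacity + 1):nrow(out), ]
  }
  attr(out, "f_cam") <- f_cam
  attr(out, "capacity") <- capacity
  class(out) <- c("breath_signal", setdiff(class(out), "breath_signal"))
  out
}

#' Write / read a breathing signal as CSV
#'
#' Column layout: `frame_index, time_s, t_min_c, px, py, roi_area`.
#'
#' @param sig A tibble with at least `frame_index`, `time_s`, `t_min_c`.
#' @param path File path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_signal_csv <- function(sig, path) {
  utils::write.csv(as.data.frame(sig), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @param f_cam Frame rate attached to the returned signal; when `NULL` it is
#'   inferred from the median spacing of `time_s`.
#' @export
read_signal_csv <- function(path, f_cam = NULL) {
  df <- tibble::as_tibble(utils::read.csv(path))
  stopifnot(all(c("time_s", "t_min_c") %in% names(df)))
  if (is.null(f_cam)) {
    f_cam <- 1 / stats::median(diff(df$time_s))
  }
  attr(df, "f_cam") <- f_cam
  df
}
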
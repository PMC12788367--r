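# End-to-end pipeline: frames (or a pre-extracted signal) to respiratory
# rate.
#
# Frame path: decode each raw frame into a calibrated temperature map, run
# the detector on scheduled frames (the oracle detector against ground-truth
# ROIs, or any user-supplied detector function), advance the Kalman track,
# extract the ROI's coldest pixel, then hand the assembled signal to phase
# detection and RR estimation. Signal path: skip straight to phase
# detection.

#' Default pipeline configuration
#'
#' Nested configuration mirroring the pipeline stages; any subset can be
#' overridden from a YAML file via [read_config()].
#'
#' @return A nested list with elements `detector` (`stride`,
#'   `confidence_min`, `jitter_px`, `miss_rate`), `tracker` (`q_scale`,
#'   `r_scale`, `max_coast_frames`), `extraction` (`percentile`), `filter`
#'   (`low_hz`, `high_hz`, `order`), `phase` (see [phase_config()]), and
#'   `rr` (see [rr_config()]).
#' @export
default_config <- function() {
  list(
    detector = list(stride = 2L, confidence_min = 0.25, jitter_px = 0,
                    miss_rate = 0),
    tracker = list(q_scale = 1, r_scale = 4, max_coast_frames = 25L),
    extraction = list(percentile = 0),
    filter = list(low_hz = 0.08, high_hz = 0.7, order = 4L),
    phase = list(velocity_window = 3L, mad_window = 21L, sensitivity = 0.6,
                 epsilon = 1e-4, dwell_s = 0.15, consolidation_s = 0.3,
                 neutral = FALSE),
    rr = list(dt_min = 60 / 42, dt_max = 60 / 5, w_new = 0.6, ema_alpha = 0.7,
              warmup_ibis = 1L)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its default. Unknown keys are rejected.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A nested configuration list (see [default_config()]).
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read configuration files",
         call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  for (section in names(user)) {
    if (!section %in% names(cfg)) {
      stop("unknown configuration section: ", section, call. = FALSE)
    }
    for (key in names(user[[section]])) {
      if (!key %in% names(cfg[[section]])) {
        stop(sprintf("unknown configuration key: %s.%s", section, key),
             call. = FALSE)
      }
      cfg[[section]][[key]] <- user[[section]][[key]]
    }
  }
  cfg
}

config_to_specs <- function(cfg, f_cam) {
  list(
    spec = filter_spec(cfg$filter$low_hz, cfg$filter$high_hz, cfg$filter$order),
    phase = phase_config(
      velocity_window = cfg$phase$velocity_window,
      mad_window = cfg$phase$mad_window,
      sensitivity = cfg$phase$sensitivity,
      epsilon = cfg$phase$epsilon,
      dwell_s = cfg$phase$dwell_s,
      consolidation_s = cfg$phase$consolidation_s,
      neutral_enabled = cfg$phase$neutral
    ),
    rr = rr_config(cfg$rr$dt_min, cfg$rr$dt_max, cfg$rr$w_new, cfg$rr$ema_alpha,
                   cfg$rr$warmup_ibis),
    kalman = kalman_config(
      f_cam,
      q_scale = cfg$tracker$q_scale,
      r_scale = cfg$tracker$r_scale,
      max_coast_frames = cfg$tracker$max_coast_frames
    )
  )
}

#' Extract the breathing signal from a raw-frame stream
#'
#' Runs decode -> scheduled detection -> Kalman tracking -> coldest-pixel
#' extraction over a list of frames. The detector is either a user function
#' `function(map, k)` returning a [detection()] or `NULL`, or the built-in
#' oracle detector driven by a ground-truth ROI table (as produced by
#' [render_synthetic_video()]).
#'
#' @param frames List of [raw_frame()] objects.
#' @param f_cam Camera rate in Hz.
#' @param truth Optional tibble with per-frame `frame_index`, `x1`, `y1`,
#'   `x2`, `y2` ground-truth ROIs (enables the oracle detector).
#' @param detector Optional detector function; overrides `truth`.
#' @param cfg Nested configuration (see [default_config()]).
#' @param gain,offset Decode calibration.
#' @return A tibble with one row per frame: `frame_index`, `time_s`,
#'   `t_min_c`, `px`, `py`, `roi_area`, `roi_source`, `m_k`; frames without
#'   an ROI (before the first detection) carry `NA`s. Attribute `f_cam` and
#'   `n_detector_calls` are attached.
#' @export
extract_signal_from_frames <- function(frames, f_cam, truth = NULL,
                                       detector = NULL, cfg = default_config(),
                                       gain = 1, offset = 0) {
  stopifnot(length(frames) >= 1)
  specs <- config_to_specs(cfg, f_cam)
  stride <- cfg$detector$stride
  h <- frames[[1]]$height
  w <- frames[[1]]$width
  if (is.null(detector)) {
    if (is.null(truth)) {
      stop("either a detector function or a ground-truth ROI table is required",
           call. = FALSE)
    }
    truth_idx <- match(
      vapply(frames, function(f) f$frame_index, integer(1)),
      truth$frame_index
    )
    detector <- function(map, k) {
      i <- truth_idx[k + 1L]
      if (is.na(i)) return(NULL)
      oracle_detector(
        c(truth$x1[i], truth$y1[i], truth$x2[i], truth$y2[i]),
        frame_w = w, frame_h = h,
        jitter_px = cfg$detector$jitter_px,
        miss_rate = cfg$detector$miss_rate
      )
    }
  }
  state <- track_init(specs$kalman)
  n <- length(frames)
  rows <- vector("list", n)
  n_calls <- 0L
  for (i in seq_len(n)) {
    fr <- frames[[i]]
    k <- fr$frame_index
    planes <- split_raw_frame(fr)
    map <- decode_temperature_map(planes$thermal_msb, planes$thermal_lsb,
                                  gain, offset)
    det <- NULL
    if (is_detection_frame(k, stride)) {
      n_calls <- n_calls + 1L
      det <- detector(map, k)
      if (!is.null(det) && det$confidence < cfg$detector$confidence_min) {
        det <- NULL
      }
    }
    step <- track_step(state, k, det, specs$kalman, stride,
                       frame_w = w, frame_h = h)
    state <- step$state
    sel <- select_roi(k, det, step$roi, stride)
    if (is.null(sel)) {
      rows[[i]] <- tibble::tibble(
        frame_index = k, time_s = k / f_cam, t_min_c = NA_real_,
        px = NA_integer_, py = NA_integer_, roi_area = NA_real_,
        roi_source = NA_character_, m_k = step$m_k
      )
      next
    }
    samp <- extract_min_temperature(map, sel$roi, cfg$extraction$percentile)
    rows[[i]] <- tibble::tibble(
      frame_index = k, time_s = k / f_cam,
      t_min_c = if (is.null(samp)) NA_real_ else samp$t_min,
      px = if (is.null(samp)) NA_integer_ else samp$px,
      py = if (is.null(samp)) NA_integer_ else samp$py,
      roi_area = if (is.null(samp)) NA_real_ else samp$roi_area,
      roi_source = sel$source, m_k = step$m_k
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "f_cam") <- f_cam
  attr(out, "n_detector_calls") <- n_calls
  out
}

#' Run the full pipeline on a fixture or a signal
#'
#' Accepts a `.trf` fixture path, a list as returned by [read_trf()] or
#' [render_synthetic_video()], or a pre-extracted signal (data frame with a
#' temperature column, or a signal CSV path), and runs every remaining stage
#' through RR estimation.
#'
#' @param input Input object (see Details above).
#' @param f_cam Sampling rate; required for bare data frames without an
#'   `f_cam` attribute.
#' @param truth,detector Detector source for the frame path (see
#'   [extract_signal_from_frames()]).
#' @param cfg Nested configuration (see [default_config()]).
#' @param out_dir Optional directory; when given, the per-frame trace CSV
#'   (`trace.csv`) and a JSON run report (`report.json`) are written there.
#' @param seed Optional seed applied before any stochastic stage (oracle
#'   jitter/misses).
#' @return A list of class `pipeline_result` with `trace` (per-sample tibble:
#'   time, raw and filtered signal, velocity, threshold, phase label,
#'   held RR), `rr` (an `rr_estimate`), `signal` (the extracted or supplied
#'   signal), and `report` (list: event/IBI counts, mean RR, detector calls,
#'   config).
#' @export
run_pipeline <- function(input, f_cam = NULL, truth = NULL, detector = NULL,
                         cfg = default_config(), out_dir = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_detector_calls <- NA_integer_
  if (is.character(input) && length(input) == 1) {
    input <- if (grepl("\\.trf$", input)) read_trf(input) else read_signal_csv(input)
  }
  if (is.list(input) && !is.data.frame(input) && !is.null(input$frames)) {
    f_cam <- input$f_cam
    if (is.null(truth) && !is.null(input$truth)) truth <- input$truth
    signal <- extract_signal_from_frames(input$frames, f_cam, truth = truth,
                                         detector = detector, cfg = cfg)
    n_detector_calls <- attr(signal, "n_detector_calls")
  } else if (is.data.frame(input)) {
    signal <- input
    if (is.null(f_cam)) f_cam <- attr(input, "f_cam")
  } else {
    stop("unreadable input: expected a .trf path, frame list, data frame or CSV path",
         call. = FALSE)
  }
  stopifnot(!is.null(f_cam))
  temp_col <- if ("t_min_c" %in% names(signal)) "t_min_c" else "temp_c"
  usable <- !is.na(signal[[temp_col]])
  specs <- config_to_specs(cfg, f_cam)
  trace <- detect_phases(signal[usable, , drop = FALSE], temp_col = temp_col,
                         f_cam = f_cam, config = specs$phase, spec = specs$spec)
  rr <- estimate_rr(trace, f_cam = f_cam, config = specs$rr)
  trace$rr_bpm <- rr_per_sample(rr, nrow(trace))
  g <- glance(rr)
  report <- list(
    n_samples = nrow(trace),
    duration_s = nrow(trace) / f_cam,
    f_cam = f_cam,
    n_exhale_onsets = g$n_onsets,
    n_valid_ibis = g$n_valid,
    n_invalid_ibis = g$n_invalid,
    rr_mean_bpm = g$rr_mean,
    rr_last_bpm = g$rr_last,
    n_detector_calls = n_detector_calls,
    config = cfg
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(trace), file.path(out_dir, "trace.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(
    list(trace = trace, rr = rr, signal = signal, report = report),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<pipeline_result> %.1f s at %g Hz: %d onsets, %d valid IBIs, mean RR %.2f BPM\n",
    r$duration_s, r$f_cam, r$n_exhale_onsets, r$n_valid_ibis, r$rr_mean_bpm
  ))
  invisible(x)
}
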
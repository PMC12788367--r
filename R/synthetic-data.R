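# Ground-truthed synthetic breathing signals and thermal scenes.
#
# The signal generator follows the quasi-periodic model
#   T(t) = T0 + A sin(2 pi f_RR t + phi) + d_low(t) + n_high(t):
# a baseline nostril temperature, a sinusoid at the respiratory frequency, a
# slow drift (modeled as a low-frequency sinusoid), and white high-frequency
# noise. The scene renderer embeds this signal as the minimum of a cold
# circular nostril blob on a warm elliptical face over a cooler ambient
# background, encoded through the raw-frame codec, with the ROI trajectory
# and per-frame signal returned as ground truth -- so every pipeline stage is
# testable hermetically.

#' Simulate a nostril-temperature breathing signal
#'
#' @param duration_s Signal duration in seconds.
#' @param f_cam Sampling (camera) rate in Hz; must exceed twice the
#'   respiratory frequency.
#' @param rate_bpm True respiratory rate in breaths per minute
#'   (`f_RR = rate_bpm / 60` Hz).
#' @param t0 Baseline nostril temperature in degrees Celsius (default 29).
#' @param amplitude Oscillation amplitude A in degrees Celsius (default 1.5).
#' @param phase Phase phi in radians (default 0).
#' @param drift_amp Amplitude of the slow drift sinusoid in degrees Celsius
#'   (default 0.3; set 0 to disable).
#' @param drift_period_s Drift period in seconds (default 120).
#' @param noise_sd Standard deviation of the white noise in degrees Celsius
#'   (default 0.15).
#' @param seed Optional integer seed; fixed seeds give identical signals.
#' @return A tibble with columns `frame_index`, `time_s`, `temp_c` (noisy
#'   sample), `clean_c` (noiseless sample), `phase_truth` (+1 while the
#'   breathing component warms, -1 while it cools), and attributes `f_cam`
#'   and `rate_bpm`.
#' @export
simulate_breath_signal <- function(duration_s = 60, f_cam = 25, rate_bpm = 18,
                                   t0 = 29, amplitude = 1.5, phase = 0,
                                   drift_amp = 0.3, drift_period_s = 120,
                                   noise_sd = 0.15, seed = NULL) {
  stopifnot(duration_s > 0, f_cam > 0, amplitude >= 0, noise_sd >= 0,
            drift_amp >= 0, drift_period_s > 0)
  f_rr <- rate_bpm / 60
  if (f_cam <= 2 * f_rr) {
    stop("aliasing: f_cam must exceed twice the respiratory frequency",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration_s * f_cam))
  k <- 0:(n - 1)
  t <- k / f_cam
  breath <- amplitude * sin(2 * pi * f_rr * t + phase)
  drift <- if (drift_amp > 0) {
    drift_amp * sin(2 * pi * t / drift_period_s)
  } else {
    rep(0, n)
  }
  noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else rep(0, n)
  clean <- t0 + breath + drift
  # truth phase from the sign of the breathing component's derivative:
  # warming (cos > 0) is exhalation
  truth <- ifelse(cos(2 * pi * f_rr * t + phase) >= 0, 1L, -1L)
  out <- tibble::tibble(
    frame_index = k,
    time_s = t,
    temp_c = clean + noise,
    clean_c = clean,
    phase_truth = truth
  )
  attr(out, "f_cam") <- f_cam
  attr(out, "rate_bpm") <- rate_bpm
  out
}

#' Synthetic thermal-scene parameters
#'
#' Defaults describe a plausible desk-scale scene: a 256x192 frame, 22 C
#' ambient background, 34 C facial ellipse, and a cold nostril blob of
#' radius 6 px whose minimum follows the breathing signal.
#'
#' @param frame_h,frame_w Frame dimensions in pixels.
#' @param ambient_c Background temperature (degrees C).
#' @param face_c Face-ellipse temperature (degrees C); must stay above the
#'   warmest signal sample so the nostril remains the coldest ROI feature.
#' @param blob_radius Nostril blob radius in pixels.
#' @param roi_margin Margin added around the blob to form the ground-truth
#'   ROI box, in pixels.
#' @param nostril_x,nostril_y Base blob center (defaults: frame center
#'   horizontally, 60% height vertically).
#' @param motion_amp_px Amplitude of a sinusoidal ROI drift (default 0,
#'   static scene).
#' @param motion_period_s Period of the ROI drift in seconds.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(frame_h = 192, frame_w = 256, ambient_c = 22,
                         face_c = 34, blob_radius = 6, roi_margin = 2,
                         nostril_x = NULL, nostril_y = NULL,
                         motion_amp_px = 0, motion_period_s = 8) {
  if (is.null(nostril_x)) nostril_x <- frame_w / 2
  if (is.null(nostril_y)) nostril_y <- frame_h * 0.6
  stopifnot(frame_h >= 16, frame_w >= 16, blob_radius >= 2,
            motion_amp_px >= 0, motion_period_s > 0)
  structure(
    list(
      frame_h = as.integer(frame_h), frame_w = as.integer(frame_w),
      ambient_c = ambient_c, face_c = face_c,
      blob_radius = blob_radius, roi_margin = roi_margin,
      nostril_x = nostril_x, nostril_y = nostril_y,
      motion_amp_px = motion_amp_px, motion_period_s = motion_period_s
    ),
    class = "scene_params"
  )
}

# ambient background with a warm face ellipse, computed once per scene
render_scene_background <- function(scene) {
  h <- scene$frame_h
  w <- scene$frame_w
  x <- matrix(rep(0:(w - 1), each = h), nrow = h)
  y <- matrix(rep(0:(h - 1), times = w), nrow = h)
  fx <- (w - 1) / 2
  fy <- (h - 1) * 0.45
  ax <- w * 0.30
  ay <- h * 0.42
  inside <- ((x - fx) / ax)^2 + ((y - fy) / ay)^2 <= 1
  bg <- matrix(scene$ambient_c, nrow = h, ncol = w)
  bg[inside] <- scene$face_c
  bg
}

#' Render a breathing signal into a synthetic raw thermal video
#'
#' Each frame is the scene background (ambient + warm face ellipse) with a
#' cold circular nostril blob centered on the ground-truth trajectory; the
#' blob's minimum equals the signal sample of that frame exactly (the codec
#' quantizes to 1/64 K). Frames are encoded through [encode_raw_frame()].
#'
#' @param signal A tibble from [simulate_breath_signal()] (or any data frame
#'   with `temp_c` and attribute `f_cam`).
#' @param scene A [scene_params()].
#' @param gain,offset Calibration used when encoding.
#' @return A list with `frames` (list of [raw_frame()]), `truth` (a tibble
#'   with per-frame `frame_index`, `x1, y1, x2, y2` ground-truth ROI and
#'   `t_min_c`), `f_cam`, and `scene`.
#' @export
render_synthetic_video <- function(signal, scene = scene_params(),
                                   gain = 1, offset = 0) {
  f_cam <- attr(signal, "f_cam")
  stopifnot(!is.null(f_cam))
  temps <- signal$temp_c
  if (max(temps) >= scene$face_c) {
    stop("scene error: face temperature must exceed the warmest signal sample",
         call. = FALSE)
  }
  h <- scene$frame_h
  w <- scene$frame_w
  r <- scene$blob_radius
  m <- scene$roi_margin
  bg <- render_scene_background(scene)
  # display plane: scene temperatures mapped linearly onto 0..255
  lo <- scene$ambient_c - 1
  hi <- scene$face_c + 1
  to_display <- function(map) {
    matrix(as.integer(pmin(pmax(round((map - lo) / (hi - lo) * 255), 0), 255)),
           nrow = h)
  }
  n <- length(temps)
  t <- signal$time_s
  cx <- scene$nostril_x +
    scene$motion_amp_px * sin(2 * pi * t / scene$motion_period_s)
  cy <- rep(scene$nostril_y, n)
  if (any(cx - r < 0) || any(cx + r > w - 1) ||
      any(cy - r < 0) || any(cy + r > h - 1)) {
    stop("scene error: nostril blob exits the frame", call. = FALSE)
  }
  frames <- vector("list", n)
  truth <- tibble::tibble(
    frame_index = signal$frame_index,
    x1 = cx - r - m, y1 = cy - r - m, x2 = cx + r + m, y2 = cy + r + m,
    t_min_c = temps
  )
  for (i in seq_len(n)) {
    map <- bg
    # local blob window around the (possibly fractional) center
    xs <- max(0, floor(cx[i] - r)):min(w - 1, ceiling(cx[i] + r))
    ys <- max(0, floor(cy[i] - r)):min(h - 1, ceiling(cy[i] + r))
    dx2 <- (xs - cx[i])^2
    dy2 <- (ys - cy[i])^2
    d2 <- outer(dy2, dx2, "+")
    inside <- d2 <= r^2
    blob <- temps[i] + (scene$face_c - temps[i]) * d2 / r^2
    win <- map[ys + 1, xs + 1, drop = FALSE]
    win[inside] <- pmin(win[inside], blob[inside])
    map[ys + 1, xs + 1] <- win
    # the pixel nearest the center carries the signal value exactly
    map[round_half_away(cy[i]) + 1, round_half_away(cx[i]) + 1] <- temps[i]
    frames[[i]] <- encode_raw_frame(map, to_display(map), gain, offset,
                                    frame_index = signal$frame_index[i])
  }
  list(frames = frames, truth = truth, f_cam = f_cam, scene = scene)
}

#' Generate a paced-breathing protocol signal
#'
#' Concatenates fixed-rate blocks (the paced-breathing protocol: e.g. 12, 18
#' and 24 breaths/min guided blocks of 60 s each) into one continuous signal.
#' The sinusoid's phase is carried across block boundaries so the waveform is
#' continuous; drift and noise run over global time.
#'
#' @param rates_bpm Numeric vector of block rates in breaths per minute
#'   (each within 5-42).
#' @param block_s Block duration in seconds (default 60).
#' @param f_cam Sampling rate in Hz.
#' @param seed Optional seed (noise reproducibility).
#' @param randomize_order Shuffle the block order (as in a randomized
#'   protocol); default FALSE.
#' @inheritParams simulate_breath_signal
#' @return A tibble like [simulate_breath_signal()] with additional columns
#'   `block` (1-based) and `rate_bpm` (the block's true rate); attributes
#'   `f_cam` and `block_s`.
#' @export
paced_protocol <- function(rates_bpm = c(12, 18, 24), block_s = 60, f_cam = 25,
                           t0 = 29, amplitude = 1.5, drift_amp = 0.3,
                           drift_period_s = 120, noise_sd = 0.15,
                           seed = NULL, randomize_order = FALSE) {
  stopifnot(all(rates_bpm >= 5), all(rates_bpm <= 42), block_s > 0)
  if (!is.null(seed)) set.seed(seed)
  if (randomize_order) rates_bpm <- sample(rates_bpm)
  n_block <- as.integer(round(block_s * f_cam))
  phase <- 0
  blocks <- vector("list", length(rates_bpm))
  for (b in seq_along(rates_bpm)) {
    f_rr <- rates_bpm[b] / 60
    k <- 0:(n_block - 1)
    t_local <- k / f_cam
    t_global <- (b - 1) * block_s + t_local
    breath <- amplitude * sin(2 * pi * f_rr * t_local + phase)
    drift <- if (drift_amp > 0) {
      drift_amp * sin(2 * pi * t_global / drift_period_s)
    } else {
      rep(0, n_block)
    }
    noise <- if (noise_sd > 0) stats::rnorm(n_block, 0, noise_sd) else rep(0, n_block)
    clean <- t0 + breath + drift
    blocks[[b]] <- tibble::tibble(
      block = b,
      rate_bpm = rates_bpm[b],
      time_s = t_global,
      temp_c = clean + noise,
      clean_c = clean,
      phase_truth = ifelse(cos(2 * pi * f_rr * t_local + phase) >= 0, 1L, -1L)
    )
    phase <- (phase + 2 * pi * f_rr * block_s) %% (2 * pi)
  }
  out <- dplyr::bind_rows(blocks)
  out$frame_index <- 0:(nrow(out) - 1)
  out <- out[, c("frame_index", "time_s", "block", "rate_bpm",
                 "temp_c", "clean_c", "phase_truth")]
  attr(out, "f_cam") <- f_cam
  attr(out, "block_s") <- block_s
  out
}
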
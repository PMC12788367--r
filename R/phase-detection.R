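# Adaptive breathing-phase detection.
#
# The band-passed nostril signal is turned into per-sample phase labels
# (-1 inhale, 0 neutral/hold, +1 exhale) by: (1) a velocity surrogate -- the
# difference of two adjacent W-sample moving averages, positive while the
# nostril warms (exhalation); (2) a symmetric adaptive threshold
# theta = alpha * MAD(recent velocities) + epsilon, which rescales itself to
# the subject's signal amplitude and noise; (3) a hysteresis state machine
# whose transitions are gated on the persistence of the outgoing state
# (minimum dwell); and (4) consolidation of A->B->A flickers whose middle
# segment is shorter than a physiological minimum.

#' Phase-detection configuration
#'
#' @param velocity_window Moving-average length W in samples (default 3).
#' @param mad_window Velocity history length L for the MAD threshold
#'   (default 21 samples; 15-25 is the sensible range).
#' @param sensitivity Threshold sensitivity alpha multiplying the MAD
#'   (default 0.6).
#' @param epsilon Small floor added to the threshold so it never degenerates
#'   to zero when the signal is flat (default 1e-4 degrees C per window).
#' @param dwell_s Minimum dwell before a state may hand over, in seconds
#'   (default 0.15).
#' @param consolidation_s Maximum duration of a flicker segment that gets
#'   merged into its flanking phase, in seconds (default 0.3).
#' @param neutral_enabled Label sub-threshold samples as neutral (0) instead
#'   of holding the previous phase (default FALSE).
#' @return A list of class `phase_config`.
#' @export
phase_config <- function(velocity_window = 3L, mad_window = 21L,
                         sensitivity = 0.6, epsilon = 1e-4,
                         dwell_s = 0.15, consolidation_s = 0.3,
                         neutral_enabled = FALSE) {
  stopifnot(
    velocity_window >= 2, mad_window >= 3, sensitivity > 0,
    epsilon > 0, dwell_s > 0, consolidation_s > 0
  )
  structure(
    list(
      velocity_window = as.integer(velocity_window),
      mad_window = as.integer(mad_window),
      sensitivity = sensitivity, epsilon = epsilon,
      dwell_s = dwell_s, consolidation_s = consolidation_s,
      neutral_enabled = isTRUE(neutral_enabled)
    ),
    class = "phase_config"
  )
}

#' Velocity surrogate: difference of adjacent moving averages
#'
#' `v[n] = mean(x[n-W+1..n]) - mean(x[n-2W+1..n-W])`. Positive values mean
#' the nostril is warming (exhalation), negative cooling (inhalation). The
#' first `2W - 1` entries have no full history and are returned as `NA`.
#'
#' @param x Numeric vector (band-passed signal).
#' @param W Window length in samples (>= 2).
#' @return Numeric vector of the same length as `x`.
#' @export
velocity_surrogate <- function(x, W = 3L) {
  stopifnot(W >= 2)
  n <- length(x)
  if (n < 2 * W) {
    stop(sprintf("not ready: need at least %d samples for W = %d, have %d",
                 2 * W, W, n), call. = FALSE)
  }
  cs <- cumsum(x)
  v <- rep(NA_real_, n)
  idx <- (2 * W):n
  lead <- (cs[idx] - cs[idx - W]) / W
  lag <- (cs[idx - W] - c(0, cs)[idx - 2 * W + 1]) / W
  v[idx] <- lead - lag
  v
}

#' MAD-adaptive symmetric threshold
#'
#' `theta = alpha * median(|v - median(v)|) + epsilon` over a window of
#' recent velocities. Scale-invariant: multiplying the window by c > 0 scales
#' `theta - epsilon` by exactly c.
#'
#' @param v_window Numeric vector of recent velocity values.
#' @param sensitivity Multiplier alpha (> 0).
#' @param epsilon Degeneracy floor (> 0, same units as `v_window`).
#' @return The threshold theta (scalar, always >= epsilon).
#' @export
mad_threshold <- function(v_window, sensitivity = 0.6, epsilon = 1e-4) {
  m <- stats::median(v_window)
  sensitivity * stats::median(abs(v_window - m)) + epsilon
}

# trailing rolling MAD threshold over the velocity sequence; NA where the
# velocity itself is NA or fewer than 3 finite values are available
rolling_mad_threshold <- function(v, L, sensitivity, epsilon) {
  n <- length(v)
  theta <- rep(NA_real_, n)
  first <- which(!is.na(v))[1]
  if (is.na(first)) return(theta)
  for (i in seq(first, n)) {
    lo <- max(first, i - L + 1)
    win <- v[lo:i]
    if (length(win) >= 3) {
      theta[i] <- mad_threshold(win, sensitivity, epsilon)
    }
  }
  theta
}

#' One step of the hysteresis phase state machine
#'
#' Transitions to +1 (exhale) when `v >= theta`, to -1 (inhale) when
#' `v <= -theta`, but only once the outgoing state has persisted at least
#' `n_min` samples; otherwise the previous label is held (or, with the
#' neutral option, sub-threshold samples become 0). The persistence counter
#' resets to 0 on a change and increments otherwise.
#'
#' @param prev_label Previous label in `{-1, 0, +1}`.
#' @param tau_prev Persistence of `prev_label` in samples.
#' @param v,theta Velocity and threshold at this sample (theta > 0).
#' @param n_min Minimum dwell in samples (>= 1).
#' @param neutral Enable the neutral sub-threshold state.
#' @return A list with `label` and `tau`.
#' @export
hysteresis_step <- function(prev_label, tau_prev, v, theta, n_min, neutral = FALSE) {
  label <- prev_label
  if (!is.na(v) && !is.na(theta)) {
    if (v >= theta && tau_prev >= n_min) {
      label <- 1L
    } else if (v <= -theta && tau_prev >= n_min) {
      label <- -1L
    } else if (neutral && abs(v) < theta) {
      label <- 0L
    }
  }
  tau <- if (label != prev_label) 0L else tau_prev + 1L
  list(label = label, tau = tau)
}

# run the hysteresis machine over whole sequences; initial state 0 with
# tau = n_min so the first genuine crossing can transition immediately
hysteresis_labels <- function(v, theta, n_min, neutral = FALSE) {
  n <- length(v)
  labels <- integer(n)
  tau <- integer(n)
  prev <- 0L
  tau_prev <- as.integer(n_min)
  for (i in seq_len(n)) {
    st <- hysteresis_step(prev, tau_prev, v[i], theta[i], n_min, neutral)
    labels[i] <- st$label
    tau[i] <- st$tau
    prev <- st$label
    tau_prev <- st$tau
  }
  list(labels = labels, tau = tau)
}

#' Merge short A->B->A flicker segments
#'
#' Every interior segment whose flanking segments share a state different
#' from its own and whose length is below `n_c` samples is relabeled to the
#' flanking state. Applied iteratively until no violation remains.
#'
#' @param labels Integer vector of phase labels.
#' @param n_c Consolidation threshold in samples (>= 1).
#' @return The consolidated label vector.
#' @export
consolidate_flicker <- function(labels, n_c) {
  stopifnot(n_c >= 1)
  repeat {
    r <- rle(labels)
    k <- length(r$lengths)
    if (k < 3) return(labels)
    changed <- FALSE
    for (i in 2:(k - 1)) {
      if (r$values[i - 1] == r$values[i + 1] &&
          r$values[i] != r$values[i - 1] &&
          r$lengths[i] < n_c) {
        r$values[i] <- r$values[i - 1]
        changed <- TRUE
      }
    }
    if (!changed) return(labels)
    labels <- inverse.rle(r)
  }
}

#' Detect breathing phases in a temperature signal
#'
#' Full phase-detection chain: zero-phase band-pass, velocity surrogate,
#' rolling MAD threshold, dwell-gated hysteresis, flicker consolidation.
#'
#' @param data A data frame with a temperature column and optionally
#'   `time_s`, or a numeric vector of samples.
#' @param temp_col Name of the temperature column (default `"t_min_c"`,
#'   falling back to `"temp_c"` if absent).
#' @param f_cam Sampling rate in Hz; taken from the `f_cam` attribute of
#'   `data` when `NULL`.
#' @param config A [phase_config()].
#' @param spec A [filter_spec()].
#' @return A tibble of class `phase_trace` with columns `time_s`, `raw_c`,
#'   `filtered`, `velocity`, `theta`, `label` and attributes `f_cam`,
#'   `config`, `spec`.
#' @export
detect_phases <- function(data, temp_col = NULL, f_cam = NULL,
                          config = phase_config(), spec = filter_spec()) {
  if (is.numeric(data) && is.null(dim(data))) {
    x <- data
    time_s <- NULL
  } else {
    stopifnot(is.data.frame(data))
    if (is.null(temp_col)) {
      temp_col <- if ("t_min_c" %in% names(data)) "t_min_c" else "temp_c"
    }
    stopifnot(temp_col %in% names(data))
    x <- data[[temp_col]]
    time_s <- data[["time_s"]]
    if (is.null(f_cam)) f_cam <- attr(data, "f_cam")
  }
  if (is.null(f_cam)) {
    stop("f_cam must be supplied or carried as an attribute of the data",
         call. = FALSE)
  }
  n <- length(x)
  min_len <- max(2 * config$velocity_window, config$mad_window,
                 3 * (2 * spec$order) + 1)
  if (n < min_len) {
    stop(sprintf("not ready: need at least %d samples, have %d", min_len, n),
         call. = FALSE)
  }
  filtered <- bandpass(x, f_cam, spec)
  v <- velocity_surrogate(filtered, config$velocity_window)
  theta <- rolling_mad_threshold(v, config$mad_window,
                                 config$sensitivity, config$epsilon)
  n_min <- max(1L, as.integer(floor(config$dwell_s * f_cam)))
  n_c <- max(1L, as.integer(floor(config$consolidation_s * f_cam)))
  hy <- hysteresis_labels(v, theta, n_min, config$neutral_enabled)
  labels <- consolidate_flicker(hy$labels, n_c)
  out <- tibble::tibble(
    time_s = if (is.null(time_s)) (seq_len(n) - 1) / f_cam else time_s,
    raw_c = x,
    filtered = filtered,
    velocity = v,
    theta = theta,
    label = as.integer(labels)
  )
  attr(out, "f_cam") <- f_cam
  attr(out, "config") <- config
  attr(out, "spec") <- spec
  class(out) <- c("phase_trace", class(out))
  out
}

#' Segment view of a phase trace
#'
#' @param trace A `phase_trace` (or plain integer label vector).
#' @return A tibble with one row per constant-label segment: `start`, `end`
#'   (1-based sample indices, inclusive), `length`, `label`.
#' @export
phase_segments <- function(trace) {
  labels <- if (is.data.frame(trace)) trace$label else trace
  r <- rle(as.integer(labels))
  ends <- cumsum(r$lengths)
  tibble::tibble(
    start = ends - r$lengths + 1L,
    end = ends,
    length = r$lengths,
    label = r$values
  )
}
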
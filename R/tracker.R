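# Constant-velocity Kalman tracking of the nostril bounding box.
#
# The state is the 8-vector (cx, cy, w, h, cx., cy., w., h.): box center,
# size, and their velocities in px and px/s. The transition matrix is the
# block form F = [[I4, dt*I4], [0, I4]] (all eigenvalues 1, marginally
# stable) and the measurement model observes the first four components,
# H = [I4 | 0]. The recursion predicts on every frame and updates only on
# scheduled frames that produced a detection; between updates the prediction
# coasts along the last velocity estimate.

#' Kalman tracker configuration
#'
#' Builds the fixed matrices of the constant-velocity tracker. The process
#' noise Q follows a white-acceleration discretization per axis
#' (`q_scale * [[dt^4/4, dt^3/2], [dt^3/2, dt^2]]` on each
#' position/velocity pair); the measurement noise is `r_scale * I4`.
#'
#' @param f_cam Camera frame rate in Hz; the step is `dt = 1/f_cam`.
#' @param q_scale Process-noise magnitude (white-acceleration spectral
#'   density, px^2/s^3-equivalent; default 1).
#' @param r_scale Measurement-noise variance per measured component
#'   (px^2; default 4).
#' @param max_coast_frames Frames the track may coast without an update
#'   before it is dropped and re-initialized on the next detection
#'   (default 25, about one second at 25 Hz).
#' @param p0_pos,p0_vel Initial variance for position/size terms and for
#'   velocity terms (px^2 and (px/s)^2; defaults 100 and 625).
#' @return A list of class `kalman_config` with elements `dt`, `F`, `H`,
#'   `Q`, `R`, `P0`, `max_coast_frames`.
#' @export
kalman_config <- function(f_cam, q_scale = 1, r_scale = 4, max_coast_frames = 25L,
                          p0_pos = 100, p0_vel = 625) {
  stopifnot(f_cam > 0, q_scale > 0, r_scale > 0, max_coast_frames >= 1)
  dt <- 1 / f_cam
  F_mat <- diag(8)
  F_mat[cbind(1:4, 5:8)] <- dt
  H_mat <- cbind(diag(4), matrix(0, 4, 4))
  Q <- matrix(0, 8, 8)
  for (i in 1:4) {
    Q[i, i] <- dt^4 / 4
    Q[i, i + 4] <- Q[i + 4, i] <- dt^3 / 2
    Q[i + 4, i + 4] <- dt^2
  }
  Q <- q_scale * Q
  structure(
    list(
      dt = dt, F = F_mat, H = H_mat, Q = Q, R = r_scale * diag(4),
      P0 = diag(c(rep(p0_pos, 4), rep(p0_vel, 4))),
      max_coast_frames = as.integer(max_coast_frames)
    ),
    class = "kalman_config"
  )
}

#' Convert a detection box to a measurement vector
#'
#' `z = ((x1+x2)/2, (y1+y2)/2, x2-x1, y2-y1)`: box center and size.
#'
#' @param det A [detection()] or numeric `c(x1, y1, x2, y2)`.
#' @return Numeric 4-vector `c(cx, cy, w, h)`.
#' @export
bbox_to_measurement <- function(det) {
  if (inherits(det, "detection")) det <- c(det$x1, det$y1, det$x2, det$y2)
  stopifnot(length(det) == 4)
  if (det[3] < det[1] || det[4] < det[2]) {
    stop("invalid box: corners are inverted", call. = FALSE)
  }
  c(
    (det[1] + det[3]) / 2, (det[2] + det[4]) / 2,
    det[3] - det[1], det[4] - det[2]
  )
}

#' Reconstruct corner coordinates from a track state
#'
#' `(x1, y1, x2, y2) = (cx - w/2, cy - h/2, cx + w/2, cy + h/2)`, with
#' width/height clamped to be non-negative and, when frame dimensions are
#' given, corners clipped to the frame.
#'
#' @param state A `track_state` (see [track_init()]).
#' @param frame_w,frame_h Optional frame dimensions for clipping.
#' @return Numeric `c(x1, y1, x2, y2)`.
#' @export
state_to_bbox <- function(state, frame_w = NULL, frame_h = NULL) {
  stopifnot(inherits(state, "track_state"), state$initialized)
  cx <- state$x[1]; cy <- state$x[2]
  w <- max(state$x[3], 0); h <- max(state$x[4], 0)
  box <- c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
  if (!is.null(frame_w)) box[c(1, 3)] <- pmin(pmax(box[c(1, 3)], 0), frame_w - 1)
  if (!is.null(frame_h)) box[c(2, 4)] <- pmin(pmax(box[c(2, 4)], 0), frame_h - 1)
  box
}

#' Initialize a track state
#'
#' Uninitialized by default; the first accepted detection sets the position
#' and size components from the measurement, zero velocities, and the initial
#' covariance `P0` from the configuration.
#'
#' @param cfg A [kalman_config()].
#' @param z Optional initial measurement `c(cx, cy, w, h)`; when supplied the
#'   state starts initialized.
#' @return A list of class `track_state` with `x` (8-vector), `P` (8x8),
#'   `initialized`, `frames_since_update`.
#' @export
track_init <- function(cfg, z = NULL) {
  state <- structure(
    list(
      x = numeric(8), P = cfg$P0,
      initialized = FALSE, frames_since_update = 0L
    ),
    class = "track_state"
  )
  if (!is.null(z)) {
    stopifnot(length(z) == 4)
    state$x[1:4] <- z
    state$initialized <- TRUE
  }
  state
}

# keep P symmetric after each algebraic step
symmetrize <- function(P) (P + t(P)) / 2

#' Kalman prediction step
#'
#' `x <- F x`, `P <- F P F' + Q`: positions advance by velocity * dt,
#' velocities are unchanged, covariance inflates.
#'
#' @param state An initialized `track_state`.
#' @param cfg A [kalman_config()].
#' @return The predicted `track_state`.
#' @export
kf_predict <- function(state, cfg) {
  if (!inherits(state, "track_state") || !state$initialized) {
    stop("cannot predict: track is not initialized", call. = FALSE)
  }
  state$x <- as.numeric(cfg$F %*% state$x)
  state$P <- symmetrize(cfg$F %*% state$P %*% t(cfg$F) + cfg$Q)
  state
}

#' Kalman measurement update
#'
#' Standard innovation/gain/posterior relations: `y = z - H x`,
#' `S = H P H' + R`, `K = P H' S^-1`, `x <- x + K y`, `P <- (I - K H) P`.
#' Resets `frames_since_update`.
#'
#' @param state A predicted `track_state`.
#' @param z Measurement 4-vector `c(cx, cy, w, h)`.
#' @param cfg A [kalman_config()].
#' @return The updated `track_state`.
#' @export
kf_update <- function(state, z, cfg) {
  stopifnot(inherits(state, "track_state"), state$initialized, length(z) == 4)
  H <- cfg$H
  y <- z - as.numeric(H %*% state$x)
  S <- H %*% state$P %*% t(H) + cfg$R
  K <- tryCatch(
    state$P %*% t(H) %*% solve(S),
    error = function(e) stop("numerical failure: innovation covariance is singular",
                             call. = FALSE)
  )
  state$x <- state$x + as.numeric(K %*% y)
  state$P <- symmetrize((diag(8) - K %*% H) %*% state$P)
  state$frames_since_update <- 0L
  state
}

#' One tracking step: predict always, update when gated in
#'
#' Runs the predict step on every frame and the measurement update only when
#' the frame is on the detection schedule and a detection exists (`m_k = 1`).
#' The first usable detection initializes the track; after
#' `max_coast_frames` consecutive frames without an update the track is
#' dropped and re-initializes on the next detection.
#'
#' @param state A `track_state` (possibly uninitialized).
#' @param k Frame index (0-based).
#' @param det A [detection()] or `NULL`.
#' @param cfg A [kalman_config()].
#' @param stride Detection stride (default 2).
#' @param frame_w,frame_h Optional frame dimensions for ROI clipping.
#' @return A list with `state`, `roi` (corners, or `NULL` while no track
#'   exists), and `m_k` (1 if a measurement was used, else 0).
#' @export
track_step <- function(state, k, det = NULL, cfg, stride = 2L,
                       frame_w = NULL, frame_h = NULL) {
  usable <- !is.null(det) && is_detection_frame(k, stride)
  if (!state$initialized) {
    if (usable) {
      state <- track_init(cfg, bbox_to_measurement(det))
      return(list(state = state, roi = state_to_bbox(state, frame_w, frame_h), m_k = 1L))
    }
    return(list(state = state, roi = NULL, m_k = 0L))
  }
  state <- kf_predict(state, cfg)
  if (usable) {
    state <- kf_update(state, bbox_to_measurement(det), cfg)
    m_k <- 1L
  } else {
    state$frames_since_update <- state$frames_since_update + 1L
    m_k <- 0L
    if (state$frames_since_update > cfg$max_coast_frames) {
      # stale: drop the track; next detection re-initializes
      state$initialized <- FALSE
      return(list(state = state, roi = NULL, m_k = m_k))
    }
  }
  list(state = state, roi = state_to_bbox(state, frame_w, frame_h), m_k = m_k)
}
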
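# Respiratory-rate estimation from the consolidated phase trace.
#
# Exhalation onsets (entries into the +1 phase) delimit breaths. Consecutive
# onsets give inter-breath intervals (IBI); only intervals inside the
# physiological 5-42 breaths/min band are accepted. Each valid IBI yields an
# instantaneous rate 60/IBI, stabilized by a causal weighted update
# (0.6 new / 0.4 previous) followed by an exponential moving average with
# coefficient 0.7. Invalid intervals are dropped and do not move the
# smoothers; the displayed rate holds its last value until the next valid
# interval.

#' Respiratory-rate configuration
#'
#' @param dt_min,dt_max Inclusive IBI acceptance bounds in seconds
#'   (defaults 60/42 and 60/5, i.e. the 5-42 breaths/min band).
#' @param w_new Weight of the newest instantaneous rate in the causal
#'   weighted update (default 0.6; the previous smoothed value gets
#'   `1 - w_new`).
#' @param ema_alpha Exponential-moving-average coefficient (default 0.7).
#' @param warmup_ibis Number of initial intervals discarded as stream-start
#'   transient (default 1). The phase machine starts in a neutral state, so
#'   its first entry into exhalation can fall mid-breath; the first interval
#'   is then bounded by a spurious onset and would bias the smoothers.
#' @return A list of class `rr_config`.
#' @export
rr_config <- function(dt_min = 60 / 42, dt_max = 60 / 5,
                      w_new = 0.6, ema_alpha = 0.7, warmup_ibis = 1L) {
  stopifnot(dt_min > 0, dt_max > dt_min, w_new > 0, w_new < 1,
            ema_alpha > 0, ema_alpha <= 1, warmup_ibis >= 0)
  structure(
    list(dt_min = dt_min, dt_max = dt_max, w_new = w_new,
         ema_alpha = ema_alpha, warmup_ibis = as.integer(warmup_ibis)),
    class = "rr_config"
  )
}

#' Exhalation-onset events of a phase trace
#'
#' Sample positions `k >= 2` (1-based) where the label enters `+1` from any
#' other state.
#'
#' @param labels Integer label vector or a `phase_trace`.
#' @return Integer vector of 1-based onset positions (possibly empty).
#' @export
exhale_onsets <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  n <- length(labels)
  if (n < 2) return(integer())
  which(labels[-1] == 1L & labels[-n] != 1L) + 1L
}

#' Inter-breath intervals from event positions
#'
#' `dt_i = (k_i - k_{i-1}) / f_cam` seconds for consecutive events.
#'
#' @param events Integer vector of event sample positions.
#' @param f_cam Sampling rate in Hz (> 0).
#' @return Numeric vector of IBIs in seconds (empty for fewer than 2 events).
#' @export
compute_ibis <- function(events, f_cam) {
  stopifnot(f_cam > 0)
  if (length(events) < 2) return(numeric())
  diff(events) / f_cam
}

#' Validate an inter-breath interval
#'
#' Accepts `dt` iff `dt_min <= dt <= dt_max` (bounds inclusive).
#'
#' @param dt IBI in seconds. Vectorized.
#' @param config An [rr_config()].
#' @return Logical vector.
#' @export
validate_ibi <- function(dt, config = rr_config()) {
  dt >= config$dt_min & dt <= config$dt_max
}

#' Instantaneous respiratory rate from an IBI
#'
#' @param dt Validated IBI in seconds. Vectorized.
#' @return Rate in breaths per minute: `60 / dt`.
#' @export
instantaneous_rr <- function(dt) {
  60 / dt
}

#' Smooth a sequence of instantaneous rates
#'
#' Two cascaded causal smoothers: the weighted update
#' `RRw_i = w_new * RR_i + (1 - w_new) * RRw_{i-1}` and the EMA
#' `RRf_i = alpha * RRw_i + (1 - alpha) * RRf_{i-1}`, both seeded with the
#' first input. Outputs are convex combinations of the inputs, so they stay
#' inside the input range.
#'
#' @param rr Numeric vector of instantaneous rates (BPM), non-empty.
#' @param config An [rr_config()].
#' @return A tibble with columns `rr_inst`, `rr_weighted`, `rr_final`.
#' @export
smooth_rr <- function(rr, config = rr_config()) {
  stopifnot(length(rr) >= 1)
  n <- length(rr)
  rw <- numeric(n)
  rf <- numeric(n)
  rw[1] <- rr[1]
  rf[1] <- rw[1]
  if (n > 1) {
    for (i in 2:n) {
      rw[i] <- config$w_new * rr[i] + (1 - config$w_new) * rw[i - 1]
      rf[i] <- config$ema_alpha * rw[i] + (1 - config$ema_alpha) * rf[i - 1]
    }
  }
  tibble::tibble(rr_inst = rr, rr_weighted = rw, rr_final = rf)
}

#' Reference respiratory rate by breath tally
#'
#' `RR = n_breaths / duration * 60` BPM -- the manual-count ground-truth
#' convention (22 breaths in a 60-s recording give 22 BPM).
#'
#' @param n_breaths Number of observed breathing cycles (>= 0).
#' @param duration_s Observation duration in seconds (> 0).
#' @return Rate in breaths per minute.
#' @export
reference_rr <- function(n_breaths, duration_s) {
  if (any(duration_s <= 0)) {
    stop("duration must be positive", call. = FALSE)
  }
  stopifnot(all(n_breaths >= 0))
  n_breaths / duration_s * 60
}

#' Estimate respiratory rate from a phase trace
#'
#' Converts the consolidated labels into exhalation onsets, computes and
#' validates IBIs, and runs the smoothing cascade over the valid
#' instantaneous rates. Invalid IBIs are recorded but do not move the
#' smoothers, and the first `warmup_ibis` intervals are excluded as
#' stream-start transient (see [rr_config()]).
#'
#' @param trace A `phase_trace` from [detect_phases()] (or an integer label
#'   vector).
#' @param f_cam Sampling rate in Hz; taken from the trace attribute when
#'   `NULL`.
#' @param config An [rr_config()].
#' @return An object of class `rr_estimate`: a list with `events` (tibble of
#'   per-interval records: `event_index`, `time_s`, `ibi_s`, `valid`,
#'   `rr_inst`, `rr_weighted`, `rr_final`), `onsets` (all onset positions),
#'   `f_cam`, `config`.
#' @export
estimate_rr <- function(trace, f_cam = NULL, config = rr_config()) {
  if (is.null(f_cam)) f_cam <- attr(trace, "f_cam")
  stopifnot(!is.null(f_cam), f_cam > 0)
  onsets <- exhale_onsets(trace)
  ibis <- compute_ibis(onsets, f_cam)
  valid <- validate_ibi(ibis, config)
  warmup <- seq_along(ibis) <= config$warmup_ibis
  events <- tibble::tibble(
    event_index = if (length(onsets) >= 2) onsets[-1] else integer(),
    time_s = (if (length(onsets) >= 2) onsets[-1] - 1L else integer()) / f_cam,
    ibi_s = ibis,
    valid = valid,
    warmup = warmup,
    rr_inst = ifelse(valid & !warmup, instantaneous_rr(ibis), NA_real_)
  )
  events$rr_weighted <- NA_real_
  events$rr_final <- NA_real_
  use <- valid & !warmup
  if (any(use)) {
    sm <- smooth_rr(events$rr_inst[use], config)
    events$rr_weighted[use] <- sm$rr_weighted
    events$rr_final[use] <- sm$rr_final
  }
  structure(
    list(events = events, onsets = onsets, f_cam = f_cam, config = config),
    class = "rr_estimate"
  )
}

#' @export
print.rr_estimate <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<rr_estimate> %d exhale onsets, %d valid / %d invalid IBIs; mean final RR %.2f BPM (last %.2f)\n",
    g$n_onsets, g$n_valid, g$n_invalid,
    g$rr_mean, g$rr_last
  ))
  invisible(x)
}

#' Tidy an RR estimate into its per-interval table
#'
#' @param x An `rr_estimate`.
#' @param ... Unused.
#' @return The per-interval tibble (one row per IBI).
#' @export
tidy.rr_estimate <- function(x, ...) {
  x$events
}

#' One-row summary of an RR estimate
#'
#' @param x An `rr_estimate`.
#' @param ... Unused.
#' @return A tibble with `n_onsets`, `n_valid`, `n_invalid`, `rr_mean`
#'   (mean of the final smoothed rate over valid intervals), `rr_last`
#'   (latest final rate), `mean_ibi_s`.
#' @export
glance.rr_estimate <- function(x, ...) {
  ev <- x$events
  use <- ev$valid & !ev$warmup
  tibble::tibble(
    n_onsets = length(x$onsets),
    n_valid = sum(use),
    n_invalid = sum(!ev$valid),
    rr_mean = if (any(use)) mean(ev$rr_final[use]) else NA_real_,
    rr_last = if (any(use)) ev$rr_final[use][sum(use)] else NA_real_,
    mean_ibi_s = if (any(use)) mean(ev$ibi_s[use]) else NA_real_
  )
}

#' Per-sample RR trace with last-value hold
#'
#' Expands an event-driven estimate to one value per trace sample: the final
#' smoothed rate of the most recent valid interval is carried forward;
#' samples before the first valid interval are `NA` (warm-up).
#'
#' @param x An `rr_estimate`.
#' @param n_samples Length of the underlying trace.
#' @return Numeric vector of length `n_samples` (BPM).
#' @export
rr_per_sample <- function(x, n_samples) {
  out <- rep(NA_real_, n_samples)
  ev <- x$events[x$events$valid & !x$events$warmup, ]
  if (nrow(ev) == 0) return(out)
  for (i in seq_len(nrow(ev))) {
    from <- ev$event_index[i]
    if (from <= n_samples) out[from:n_samples] <- ev$rr_final[i]
  }
  out
}
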
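# Zero-phase Butterworth band-pass filtering.
#
# Respiration lives in 0.08-0.7 Hz (5-42 breaths/min). A Butterworth
# band-pass (design order 4) removes baseline drift and high-frequency
# sensor noise; applying it forward and backward cancels the phase response
# so breath timing is preserved. The forward-backward pass here extends the
# signal by odd reflection at both ends and starts each pass from the
# filter's constant-input steady state, which suppresses the edge transients
# a plain forward-backward recursion leaves behind (the passband is narrow,
# so transients decay over ~150 samples otherwise).

#' Band-pass filter specification
#'
#' @param low_hz,high_hz Passband edges in Hz (defaults 0.08 and 0.7,
#'   covering 5-42 breaths/min).
#' @param order Butterworth design order (default 4; the resulting band-pass
#'   has twice that many poles).
#' @param zero_phase Apply forward-backward for zero phase (default TRUE).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.08, high_hz = 0.7, order = 4L, zero_phase = TRUE) {
  stopifnot(low_hz > 0, high_hz > low_hz, order >= 1)
  structure(
    list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
         zero_phase = isTRUE(zero_phase)),
    class = "filter_spec"
  )
}

# steady-state initial conditions of the direct-form-II-transposed filter
# for a unit-step input (so z * x[1] starts the recursion at steady state)
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  A <- rbind(-a[2:n], cbind(diag(n - 2), 0))
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1) - t(A), B)
}

# direct-form-II-transposed IIR filter with explicit state vector
lfilter <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  z <- if (is.null(zi)) rep(0, n - 1) else zi
  y <- numeric(length(x))
  nz <- n - 1
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nz > 1) {
      for (j in seq_len(nz - 1)) z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    }
    z[nz] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

# forward-backward filtering with odd-reflection padding
filtfilt_pad <- function(b, a, x) {
  pad <- 3 * (max(length(a), length(b)) - 1)
  n <- length(x)
  if (n <= pad) {
    stop(sprintf("not ready: need more than %d samples to filter, have %d", pad, n),
         call. = FALSE)
  }
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi * ext[1])
  y <- rev(lfilter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase band-pass filter a breathing signal
#'
#' Designs a Butterworth band-pass for the given frame rate and applies it
#' forward-backward (zero phase). DC and slow drift are rejected; breath
#' timing is preserved.
#'
#' @param x Numeric sample vector (degrees Celsius, uniformly sampled).
#' @param f_cam Sampling (camera) rate in Hz; must exceed `2 * high_hz`.
#' @param spec A [filter_spec()].
#' @return Filtered numeric vector, same length as `x`.
#' @export
bandpass <- function(x, f_cam, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (f_cam <= 2 * spec$high_hz) {
    stop("frame rate must exceed twice the upper passband edge", call. = FALSE)
  }
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (f_cam / 2),
                       type = "pass")
  if (spec$zero_phase) {
    filtfilt_pad(bf$b, bf$a, x)
  } else {
    lfilter(bf$b, bf$a, x)
  }
}
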
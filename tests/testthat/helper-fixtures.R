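# Shared fixture builders. Everything is generated in code; no binary files.

# random temperature map in a physiological range
random_map <- function(h, w, lo = 15, hi = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::runif(h * w, lo, hi), nrow = h, ncol = w)
}

# flat display plane
flat_plane <- function(h, w, value = 128L) {
  matrix(as.integer(value), nrow = h, ncol = w)
}

# a clean sinusoidal breathing signal as a bare vector
clean_sine <- function(rate_bpm, duration_s = 60, f_cam = 25, t0 = 29, a = 1.5,
                       phase = 0) {
  t <- (0:(round(duration_s * f_cam) - 1)) / f_cam
  t0 + a * sin(2 * pi * rate_bpm / 60 * t + phase)
}

# small synthetic scene for frame-level tests
small_scene <- function(...) {
  scene_params(frame_h = 48, frame_w = 64, blob_radius = 4, roi_margin = 2,
               nostril_y = 30, ...)
}
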
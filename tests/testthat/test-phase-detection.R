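# Band-pass filtering, velocity surrogate, adaptive threshold, hysteresis,
# flicker consolidation, and the assembled phase detector.

# analytic frequency-response oracle of the designed filter: the zero-phase
# (forward-backward) gain at frequency f is |B/A|^2 evaluated on the unit
# circle
zero_phase_gain <- function(f, f_cam, spec = filter_spec()) {
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (f_cam / 2),
                       type = "pass")
  w <- 2 * pi * f / f_cam
  z <- exp(-1i * w * (seq_along(bf$b) - 1))
  Mod(sum(bf$b * z) / sum(bf$a * z))^2
}

test_that("the band-pass rejects DC and matches the frequency-response oracle", {
  f_cam <- 25
  t <- (0:1499) / f_cam
  # constant input is fully rejected
  expect_lt(max(abs(bandpass(rep(30, 1500), f_cam))), 1e-6)
  mid <- 400:1100
  # passband center: unit sinusoid survives within 5% of the oracle gain
  y03 <- bandpass(sin(2 * pi * 0.3 * t), f_cam)
  expect_equal(max(abs(y03[mid])), sqrt(zero_phase_gain(0.3, f_cam)) * 1,
               tolerance = 0.05)
  expect_gt(max(abs(y03[mid])), 0.95)
  # stopband: a 2 Hz tone is crushed, consistent with the oracle
  y2 <- bandpass(sin(2 * pi * 2 * t), f_cam)
  expect_lt(max(abs(y2[mid])), 0.1)
  expect_lt(zero_phase_gain(2, f_cam), 0.01)
  # sub-band drift is attenuated
  expect_lt(zero_phase_gain(0.01, f_cam), 0.05)
})

test_that("zero-phase filtering leaves no lag on a passband sinusoid", {
  f_cam <- 25
  t <- (0:1499) / f_cam
  x <- sin(2 * pi * 0.3 * t)
  y <- bandpass(x, f_cam)
  cc <- stats::ccf(y, x, lag.max = 15, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("too-short signals are a not-ready condition", {
  expect_error(bandpass(rep(29, 10), 25), "not ready")
  expect_error(velocity_surrogate(c(1, 2, 3), W = 3), "not ready")
})

test_that("the velocity surrogate has the closed ramp form and sign convention", {
  # constant input: zero velocity
  v <- velocity_surrogate(rep(5, 40), W = 3)
  expect_true(all(abs(v[6:40]) < 1e-12))
  expect_true(all(is.na(v[1:5]))) # first 2W-1 unavailable
  # linear ramp with slope m per sample: v = m * W everywhere valid
  for (W in c(2, 3, 5)) {
    m <- 0.25
    v <- velocity_surrogate(m * (1:60), W = W)
    expect_equal(unique(round(v[(2 * W):60], 12)), m * W)
  }
  # warming ramp -> positive v (exhalation); cooling -> negative
  expect_gt(velocity_surrogate(0.1 * (1:20), 3)[10], 0)
  expect_lt(velocity_surrogate(-0.1 * (1:20), 3)[10], 0)
})

test_that("the MAD threshold matches hand arithmetic and is scale-equivariant", {
  # constant window: dispersion zero, threshold is the epsilon floor
  expect_equal(mad_threshold(rep(3, 21), 0.6, 1e-4), 1e-4)
  # window {-2,-1,0,1,2}: median 0, MAD 1, theta = 0.6*1 + 0.001
  expect_equal(mad_threshold(c(-2, -1, 0, 1, 2), 0.6, 0.001), 0.601)
  # scaling the window by c > 0 scales (theta - eps) by exactly c
  set.seed(3)
  w <- rnorm(21)
  eps <- 1e-4
  for (c_scale in c(0.1, 10, 1234)) {
    expect_equal(mad_threshold(w * c_scale, 0.6, eps) - eps,
                 c_scale * (mad_threshold(w, 0.6, eps) - eps))
  }
})

test_that("hysteresis transitions are dwell-gated and neutral is optional", {
  # crossing with sufficient persistence transitions immediately
  expect_equal(hysteresis_step(-1L, 10L, v = 0.5, theta = 0.2, n_min = 3)$label, 1L)
  # crossing without dwell holds the previous label
  held <- hysteresis_step(1L, 1L, v = -0.5, theta = 0.2, n_min = 3)
  expect_equal(held$label, 1L)
  expect_equal(held$tau, 2L) # persistence keeps counting
  # sub-threshold with neutral enabled drops to 0
  expect_equal(
    hysteresis_step(1L, 10L, v = 0.05, theta = 0.2, n_min = 3, neutral = TRUE)$label,
    0L
  )
  # sub-threshold without neutral holds
  expect_equal(hysteresis_step(1L, 10L, v = 0.05, theta = 0.2, n_min = 3)$label, 1L)
  # tau resets on change
  expect_equal(hysteresis_step(-1L, 10L, v = 0.5, theta = 0.2, n_min = 3)$tau, 0L)
  # boundary inclusivity: v == theta counts as a crossing
  expect_equal(hysteresis_step(-1L, 10L, v = 0.2, theta = 0.2, n_min = 3)$label, 1L)
})

test_that("every completed hysteresis segment respects the minimum dwell", {
  set.seed(8)
  v <- rnorm(600)
  theta <- rep(0.8, 600)
  n_min <- 4L
  hy <- hysteresis_labels(v, theta, n_min)
  seg <- phase_segments(hy$labels)
  interior <- seg[-c(1, nrow(seg)), ]
  if (nrow(interior) > 0) expect_true(all(interior$length >= n_min))
})

test_that("flicker consolidation merges short middles and reaches a fixed point", {
  expect_equal(
    consolidate_flicker(rep(c(1, -1, 1), c(10, 2, 5)), n_c = 3),
    rep(1, 17)
  )
  # middle segment long enough: unchanged
  keep <- rep(c(1, -1, 1), c(10, 5, 5))
  expect_equal(consolidate_flicker(keep, n_c = 3), keep)
  # nested flickers resolve by iterating to a fixed point
  expect_equal(
    consolidate_flicker(rep(c(1, 0, 1, 0, 1), c(6, 1, 1, 1, 6)), n_c = 3),
    rep(1, 15)
  )
  # fixed-point output has no remaining A->B->A violation (scan assertion)
  set.seed(12)
  for (i in 1:20) {
    labs <- consolidate_flicker(sample(c(-1L, 0L, 1L), 200, TRUE), n_c = 5)
    seg <- phase_segments(labs)
    if (nrow(seg) >= 3) {
      for (j in 2:(nrow(seg) - 1)) {
        violation <- seg$label[j - 1] == seg$label[j + 1] &&
          seg$label[j] != seg$label[j - 1] && seg$length[j] < 5
        expect_false(violation)
      }
    }
  }
})

test_that("a noiseless sinusoid yields alternating phases with ~f_RR*60s exhale segments", {
  sig <- clean_sine(rate_bpm = 18, duration_s = 60)
  trace <- detect_phases(sig, f_cam = 25)
  seg <- phase_segments(trace)
  n_exhale <- sum(seg$label == 1)
  expect_gte(n_exhale, 17)
  expect_lte(n_exhale, 19)
  # labels alternate -1/+1 after the initial neutral run
  body <- seg$label[seg$label != 0]
  expect_true(all(abs(diff(body)) == 2))
  # constant signal: one unbroken segment, no transitions
  const_trace <- detect_phases(rep(29, 1500), f_cam = 25)
  expect_equal(nrow(phase_segments(const_trace)), 1)
  expect_equal(unique(const_trace$label), 0L)
})

test_that("a single large spike does not add phase segments", {
  sig <- clean_sine(rate_bpm = 18, duration_s = 60)
  spiked <- sig
  spiked[700] <- spiked[700] + 15 # 10x the breathing amplitude
  clean_seg <- phase_segments(detect_phases(sig, f_cam = 25))
  spike_seg <- phase_segments(detect_phases(spiked, f_cam = 25))
  expect_equal(nrow(spike_seg), nrow(clean_seg))
})

test_that("phase labels are invariant to signal amplitude scaling", {
  sig <- clean_sine(rate_bpm = 15, duration_s = 50)
  base <- detect_phases(sig, f_cam = 25)$label
  for (c_scale in c(0.1, 10)) {
    scaled <- detect_phases(29 + (sig - 29) * c_scale, f_cam = 25)$label
    expect_equal(scaled, base)
  }
})

test_that("not-ready and neutral-enabled paths behave", {
  expect_error(detect_phases(rep(29, 10), f_cam = 25), "not ready")
  sig <- clean_sine(rate_bpm = 18, duration_s = 40)
  tr <- detect_phases(sig, f_cam = 25,
                      config = phase_config(neutral_enabled = TRUE))
  # with neutral enabled, hold states appear between phases
  expect_true(all(c(-1L, 0L, 1L) %in% tr$label))
})
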
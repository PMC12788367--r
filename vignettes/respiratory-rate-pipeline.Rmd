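---
title: "Estimating respiratory rate from thermal video: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating respiratory rate from thermal video: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 3.5)
library(thermobreath)
```

## The measurement principle

Air inhaled through the nose is at ambient temperature and cools the nostril
rim; exhaled air is near core temperature and warms it. A radiometric thermal
camera pointed at the face therefore sees a small oscillation — a few tenths
of a degree up to about 1.5 °C — in the coldest pixels of the nostril region,
at exactly the breathing frequency. `thermobreath` turns that observation
into a respiratory-rate (RR) estimate through a chain of stages, each of
which is exposed as an ordinary function operating on data frames:

1. **Frame decoding.** Each dual-stream capture carries a display image plane
   and a thermal plane of two bytes per pixel. The 16-bit word
   `256·MSB + LSB` encodes Kelvin × 64, so
   `(256·MSB + LSB)/64 − 273.15` is the temperature in °C, refined by a
   linear calibration `T = gain · R + offset` (defaults `gain = 1`,
   `offset = 0`: no fitted calibration values are assumed).
2. **Scheduled detection + Kalman tracking.** A nostril detector runs only on
   every second frame (`stride = 2`), halving its cost; an
   8-state constant-velocity Kalman filter (box center, size, and their
   velocities) predicts the region of interest (ROI) on the skipped frames
   and through missed detections.
3. **Coldest-pixel extraction.** The per-frame minimum temperature inside the
   tracked ROI forms a 1-D breathing signal, kept in a sliding buffer of
   about 20 s (`N = ⌈20 · f_cam⌉` samples).
4. **Phase detection.** The signal is band-pass filtered to 0.08–0.7 Hz
   (5–42 breaths/min) with a zero-phase Butterworth filter; a velocity
   surrogate, an adaptive MAD threshold, a dwell-gated hysteresis state
   machine, and a flicker-consolidation pass produce stable inhale / exhale
   (/hold) labels.
5. **Rate estimation.** Exhalation onsets delimit breaths; inter-breath
   intervals (IBIs) are validated against the physiological band and
   converted to instantaneous rates `60/Δt`, then smoothed by a weighted
   update (0.6 new / 0.4 previous) and an exponential moving average
   (coefficient 0.7).

The trained neural nostril detector of a real deployment is deliberately
**not** part of this package. The detector is a contract — a function taking
a temperature map and returning a box with a confidence — and the package
ships a ground-truth-driven *oracle detector* with configurable jitter and
miss rate, so that the tracking, extraction and estimation stages are
testable hermetically.

## The phase detector in detail

All phase logic operates on the band-passed signal `x[n]`:

* **Velocity surrogate.** `v[n]` is the difference between two adjacent
  moving averages of length `W` (default 3 samples):
  `v[n] = mean(x[n−W+1..n]) − mean(x[n−2W+1..n−W])`. On a linear ramp of
  slope `m` per sample this equals `m·W` exactly; its sign is positive while
  the nostril warms, i.e. during exhalation. The first `2W − 1` samples have
  no full history and are treated as unavailable.
* **Adaptive threshold.** `θ[n] = α · MAD(v over the last L samples) + ε`,
  with sensitivity `α = 0.6`, history `L = 21` samples (a 0.84-s window at
  25 Hz; 15–25 is the sensible range), and floor `ε = 10⁻⁴` °C/window so the
  threshold never degenerates on a flat signal. Because the MAD scales
  linearly with the data, the detected phase pattern is invariant to signal
  amplitude whenever `α·MAD ≫ ε` — no per-subject gain tuning.
* **Hysteresis with dwell.** The label switches to +1 when `v ≥ θ` and to −1
  when `v ≤ −θ` (ties inclusive), but only once the *outgoing* state has
  persisted `N_min = ⌊0.15 s · f_cam⌋` samples; otherwise the previous label
  holds. A neutral sub-threshold state (label 0) is implemented but disabled
  by default — event extraction only needs entries into +1, and the gating
  is exactly as the update rule prints it (exit-dwell, not entry-dwell).
* **Flicker consolidation.** Any interior segment shorter than
  `N_c = ⌊0.3 s · f_cam⌋` samples whose two neighbours share a different
  state (an A→B→A pattern) is merged into the flanking state, iterating to a
  fixed point. After this pass no implausible micro-segment remains, which
  the test suite asserts by scanning.

**Initialization.** The machine starts in the neutral state with its
persistence counter pre-loaded to `N_min`, so the first genuine crossing can
transition immediately. The threshold needs at least 3 velocity samples and
uses a growing window until `L` samples exist.

## From phases to a rate

Exhalation onsets are samples where the label enters +1 from any other
state. Consecutive onsets give IBIs `Δt_i`; only
`60/42 s ≤ Δt_i ≤ 60/5 s` (inclusive) are accepted, which confines every
reported instantaneous rate to 5–42 BPM. Both smoothers are convex
combinations, so the final output inherits that band — a property the tests
check on randomized label sequences.

Two estimation-stage policies deserve justification:

* **Warm-up interval (`warmup_ibis = 1`).** At stream start the machine
  leaves its neutral state at the first threshold crossing, which can fall
  mid-exhale; the first "onset" is then not a breath boundary, and the first
  IBI would be spuriously short. The first interval is therefore discarded
  before smoothing. On a continuous monitoring stream this costs one breath
  once; on 60-s benchmark records it removes a visible startup bias (about
  +0.7 BPM at 18 BPM) without touching any threshold.
* **Rejection behaviour.** Invalid IBIs are dropped, not clamped, and do not
  advance the smoothers; the displayed rate holds its last value until the
  next valid interval, and nothing is reported before the first one.

## Numerical choices

* **Filter design and application.** "4th-order Butterworth band-pass" is
  read in the design-order convention (`butter(4, …)`, giving an 8-pole
  band-pass). Coefficients come from `signal::butter`; the zero-phase pass
  is implemented in the package as a forward–backward recursion with
  odd-reflection padding of `3·(n−1)` samples and steady-state initial
  conditions per pass. The padding matters: the passband is narrow (poles
  with modulus ≈ 0.994 at 25 Hz), so an unpadded forward–backward pass
  leaves edge transients of more than 100 samples, while the padded version
  attenuates a constant input below 10⁻⁶ °C.
* **Coordinates and ties.** Pixel coordinates are 0-based with x = column
  and y = row; all argmin/argmax ties break row-major-first. Real-valued
  tracker boxes are rounded half-away-from-zero before the inclusive
  integer ROI is read; ROIs partially outside the frame are clipped (an
  empty intersection yields no sample for that frame).
* **Raw-frame layout.** The on-disk `.trf` fixture format is declared
  normative for this package: a 16-byte little-endian header (magic `TRF1`,
  height, width, frame rate, frame count) followed by per-frame payloads —
  image plane (`H·W` single-byte intensities, row-major), then thermal plane
  (`H·W` MSB,LSB pairs, row-major). A self-consistent byte-exact layout is
  preferable to imitating an undocumented device dialect; the display plane
  is stored as single-byte grayscale because the visualization branch
  carries no quantitative role.
* **Tracker noise.** Process noise follows a white-acceleration
  discretization per axis with magnitude `q_scale = 1`; measurement noise is
  `4·I₄` px²; the initial covariance is 10² px² on positions/sizes and
  25² (px/s)² on velocities; a track is dropped after 25 frames (≈1 s at
  25 Hz) without an update and re-initializes on the next detection. These
  magnitudes are standard constant-velocity-tracker practice, declared here
  because no fitted values exist to adopt.
* **Baselines.** The peak baseline counts local maxima of the band-passed
  signal with topographic prominence above 0.2 × its standard deviation and
  spacing of at least 60/42 s, and divides by the record duration. The
  spectral baseline linearly detrends, applies a Hann window, zero-pads
  eightfold, and takes the largest periodogram magnitude in 0.08–0.7 Hz
  (ties to the lower frequency); when the in-band maximum is below one tenth
  of the full-spectrum maximum the estimator reports "not ready" rather
  than a rate.

## The synthetic generator: what it does and does not emulate

The generator realizes a quasi-periodic signal model — baseline + sinusoid
at the respiratory frequency + slow drift + white noise:

```{r model}
sig <- simulate_breath_signal(duration_s = 60, f_cam = 25, rate_bpm = 18,
                              t0 = 29, amplitude = 1.5, drift_amp = 0.3,
                              drift_period_s = 120, noise_sd = 0.15, seed = 1)
head(sig, 3)
```

Scene rendering places that signal as the minimum of a cold circular blob
(radius 6 px) on a 34 °C facial ellipse over a 22 °C background in a
256 × 192 frame, with an optional sinusoidal ROI trajectory and
ground-truth boxes returned alongside. The defaults — baseline 29 °C,
amplitude 1.5 °C, drift 0.3 °C over 120 s, noise 0.15 °C — are plausible
magnitudes for a close-range consumer thermal camera, declared once as this
package's study conditions rather than measured values.

What the generator does **not** emulate, and what that means for the tests:
head pose changes, articulation, partial occlusion, amplitude
non-stationarity, and the pixel-level texture of real faces. Passing the
synthetic benchmarks therefore demonstrates that the *algorithmic chain is
correct and self-consistent* — it recovers known rates from signals obeying
its model — not that real-world accuracy matches any particular figure.
The consequence is visible in the method comparison: on stationary
sinusoidal records a 60-s window contains exactly `rate` signal maxima, so
the peak-counting baseline is error-free by construction, and a windowed
periodogram is near-optimal for a single tone. The robustness advantages of
adaptive phase detection only manifest on data with artifacts and
non-stationarity, which this generator deliberately does not fabricate.

## A worked run

```{r run}
trace <- detect_phases(sig, temp_col = "temp_c")
rr <- estimate_rr(trace)
glance(rr)
```

```{r plots}
autoplot(trace)
autoplot(rr)
```

Frame-level runs work the same way at any scale; the test suite exercises
them on reduced scenes (64 × 48 px, 25–30 s) to keep runs fast, and the
package-level benchmarks use 30 signal-level records of 60 s at 25 Hz — the
problem sizes at which all reported numbers in the README were computed.

## Known limitations

* The detector contract is only exercised by the oracle; integrating a real
  trained detector is a user-side plug-in.
* Streaming operation re-applies the zero-phase filter to the whole sliding
  buffer per sample, which is how a zero-phase response and causal output
  coexist at buffer level; the newest label is then the streaming output.
  The offline functions process a whole record at once instead.
* Mouth breathing, occluded nostrils, and low thermal contrast defeat the
  physical premise; no attempt is made to detect or flag these regimes.
* The IBI validation band (5–42 BPM) silently discards genuinely
  pathological rates outside it.
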
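# Error metrics and the two baseline rate estimators.
#
# The baselines are deliberately simple references: counting
# prominence-gated peaks of the band-passed signal, and the dominant
# frequency of a Hann-windowed periodogram restricted to the respiratory
# band. Both see exactly the same input as the proposed phase/IBI method in
# any comparison here.

#' Mean absolute and root-mean-square error
#'
#' @param estimates,references Numeric vectors of equal length (>= 1), BPM.
#' @return A tibble with columns `mae` and `rmse`.
#' @export
mae_rmse <- function(estimates, references) {
  if (length(estimates) != length(references) || length(estimates) < 1) {
    stop("estimates and references must have equal positive length",
         call. = FALSE)
  }
  err <- estimates - references
  tibble::tibble(mae = mean(abs(err)), rmse = sqrt(mean(err^2)))
}

# local maxima with scipy-style topographic prominence
find_peaks <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  idx
}

peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    height <- x[p]
    # walk left until a strictly higher sample (or the boundary)
    left_min <- height
    i <- p - 1L
    while (i >= 1 && x[i] <= height) {
      if (x[i] < left_min) left_min <- x[i]
      i <- i - 1L
    }
    right_min <- height
    i <- p + 1L
    while (i <= length(x) && x[i] <= height) {
      if (x[i] < right_min) right_min <- x[i]
      i <- i + 1L
    }
    height - max(left_min, right_min)
  }, numeric(1))
}

#' Baseline: respiratory rate by peak counting
#'
#' Counts local maxima of the band-passed signal whose prominence exceeds a
#' fixed fraction of the signal's standard deviation and whose spacing
#' respects a minimum separation; the rate is `peaks / duration * 60`.
#'
#' @param filtered Numeric band-passed signal.
#' @param f_cam Sampling rate in Hz.
#' @param min_separation_s Minimum peak spacing in seconds (default 60/42,
#'   the fastest physiological breath).
#' @param prominence_frac Prominence gate as a fraction of `sd(filtered)`
#'   (default 0.2).
#' @return Estimated rate in BPM (0 for a flat signal).
#' @export
baseline_peak_rr <- function(filtered, f_cam, min_separation_s = 60 / 42,
                             prominence_frac = 0.2) {
  n <- length(filtered)
  if (n < 3 || n / f_cam < 2 * min_separation_s) {
    stop("not ready: signal too short for peak counting", call. = FALSE)
  }
  s <- stats::sd(filtered)
  if (s == 0) return(0)
  peaks <- find_peaks(filtered)
  if (length(peaks) == 0) return(0)
  prom <- peak_prominence(filtered, peaks)
  peaks <- peaks[prom >= prominence_frac * s]
  if (length(peaks) == 0) return(0)
  # enforce separation: keep highest peaks first, drop close neighbours
  min_gap <- min_separation_s * f_cam
  ord <- order(filtered[peaks], decreasing = TRUE)
  kept <- integer()
  for (p in peaks[ord]) {
    if (all(abs(kept - p) >= min_gap)) kept <- c(kept, p)
  }
  length(kept) / (n / f_cam) * 60
}

#' Baseline: respiratory rate by spectral peak
#'
#' Linearly detrends the signal, applies a Hann window, and returns 60 times
#' the frequency of the largest periodogram magnitude inside the respiratory
#' band (ties resolve to the lower frequency). When the in-band maximum is
#' below one tenth of the full-spectrum maximum (DC excluded) -- e.g. the
#' record is pure sub-band drift -- the estimator is not ready and returns
#' `NA`.
#'
#' @param x Numeric signal (raw or filtered).
#' @param f_cam Sampling rate in Hz.
#' @param low_hz,high_hz Respiratory band (defaults 0.08 and 0.7 Hz).
#' @param min_duration_s Minimum record length in seconds (default 20).
#' @return Estimated rate in BPM, or `NA_real_` when no in-band peak stands
#'   above the floor.
#' @export
baseline_fft_rr <- function(x, f_cam, low_hz = 0.08, high_hz = 0.7,
                            min_duration_s = 20) {
  n <- length(x)
  if (n / f_cam < min_duration_s) {
    stop(sprintf("not ready: need at least %g s of samples", min_duration_s),
         call. = FALSE)
  }
  t <- seq_len(n)
  x <- stats::residuals(stats::lm(x ~ t))
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)) # Hann
  xw <- x * w
  nfft <- 2^ceiling(log2(n)) * 8L # zero-pad for a fine frequency grid
  mag <- Mod(stats::fft(c(xw, rep(0, nfft - n)))[1:(nfft %/% 2 + 1)])
  freq <- (0:(nfft %/% 2)) * f_cam / nfft
  in_band <- freq >= low_hz & freq <= high_hz
  full <- freq > 0
  if (!any(in_band)) return(NA_real_)
  if (max(mag[in_band]) < 0.1 * max(mag[full])) return(NA_real_)
  # which.max returns the first (lowest-frequency) maximum: declared tie rule
  60 * freq[in_band][which.max(mag[in_band])]
}

#' Evaluate the pipeline over labeled fixed-rate blocks
#'
#' Runs phase detection and RR estimation independently on each block of a
#' [paced_protocol()]-style data frame, compares each block's mean final
#' smoothed rate to the block's true rate, and aggregates MAE/RMSE.
#'
#' @param data A data frame with columns `block`, `rate_bpm`, `temp_c` (and
#'   optionally `time_s`), e.g. from [paced_protocol()].
#' @param f_cam Sampling rate in Hz (attribute of `data` when `NULL`).
#' @param config A [phase_config()].
#' @param spec A [filter_spec()].
#' @param rr_cfg An [rr_config()].
#' @return A list of class `evaluation_report`: `per_block` tibble
#'   (`block`, `rate_true`, `rr_est`, `error`, `n_valid_ibis`), `mae`,
#'   `rmse`, `n_blocks`.
#' @export
evaluate_blocks <- function(data, f_cam = NULL, config = phase_config(),
                            spec = filter_spec(), rr_cfg = rr_config()) {
  stopifnot(all(c("block", "rate_bpm", "temp_c") %in% names(data)))
  if (is.null(f_cam)) f_cam <- attr(data, "f_cam")
  stopifnot(!is.null(f_cam))
  per_block <- data |>
    dplyr::group_by(.data$block) |>
    dplyr::group_map(function(df, key) {
      trace <- detect_phases(df$temp_c, f_cam = f_cam, config = config,
                             spec = spec)
      rr <- estimate_rr(trace, f_cam = f_cam, config = rr_cfg)
      g <- glance(rr)
      tibble::tibble(
        block = key$block,
        rate_true = df$rate_bpm[1],
        rr_est = g$rr_mean,
        n_valid_ibis = g$n_valid
      )
    }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(error = .data$rr_est - .data$rate_true)
  m <- mae_rmse(per_block$rr_est, per_block$rate_true)
  structure(
    list(per_block = per_block, mae = m$mae, rmse = m$rmse,
         n_blocks = nrow(per_block)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d blocks, MAE %.3f BPM, RMSE %.3f BPM\n",
              x$n_blocks, x$mae, x$rmse))
  print(x$per_block)
  invisible(x)
}
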
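# Dual-stream raw thermal frame codec.
#
# A capture from the thermal camera carries two planes: a display image plane
# (one byte per pixel here) and a radiometric thermal plane of two bytes per
# pixel (MSB, LSB). The 16-bit word 256*MSB + LSB encodes Kelvin * 64, so
# (256*MSB + LSB)/64 - 273.15 is the temperature proxy in degrees Celsius,
# refined by a linear calibration gain/offset.
#
# Conventions: coordinates are 0-based with x = column and y = row; matrices
# are indexed [y + 1, x + 1]; all byte layouts are row-major; ties in
# argmax/argmin are broken row-major-first (smallest y, then smallest x).

KELVIN_OFFSET <- 273.15
THERMAL_LSB_K <- 1 / 64 # quantization step of the 16-bit word, in Kelvin

#' Construct a raw dual-stream thermal frame
#'
#' Bundles a byte payload with its dimensions and frame index. The payload
#' must hold exactly `H*W` image-plane bytes followed by `2*H*W` thermal-plane
#' bytes (row-major, MSB then LSB per pixel).
#'
#' @param payload Raw vector of length `3 * height * width`.
#' @param height,width Frame dimensions in pixels (single modality).
#' @param frame_index Non-negative integer index of the frame in its stream.
#' @return An object of class `raw_frame`.
#' @seealso [split_raw_frame()], [encode_raw_frame()], [read_trf()]
#' @export
raw_frame <- function(payload, height, width, frame_index = 0L) {
  stopifnot(is.raw(payload), height >= 1, width >= 1, frame_index >= 0)
  expected <- as.integer(3 * height * width)
  if (length(payload) != expected) {
    stop(sprintf(
      "malformed frame: payload has %d bytes, expected %d (= 3 * %d * %d) for a %dx%d dual-stream frame",
      length(payload), expected, height, width, width, height
    ), call. = FALSE)
  }
  structure(
    list(
      payload = payload,
      height = as.integer(height),
      width = as.integer(width),
      frame_index = as.integer(frame_index)
    ),
    class = "raw_frame"
  )
}

#' @export
print.raw_frame <- function(x, ...) {
  cat(sprintf(
    "<raw_frame> %dx%d px, frame %d, %d payload bytes\n",
    x$width, x$height, x$frame_index, length(x$payload)
  ))
  invisible(x)
}

# row-major byte vector -> R matrix [y+1, x+1]
bytes_to_matrix <- function(bytes, height, width) {
  matrix(as.integer(bytes), nrow = height, ncol = width, byrow = TRUE)
}

matrix_to_bytes <- function(mat) {
  as.raw(as.integer(t(mat)))
}

#' Split a raw frame into its image and thermal planes
#'
#' Divides the dual-stream payload into the display image plane (one byte per
#' pixel) and the radiometric thermal plane (an MSB and an LSB byte per
#' pixel). Re-encoding the returned planes reproduces the payload
#' byte-for-byte.
#'
#' @param frame A [raw_frame()].
#' @return A list with integer matrices `image_plane` (HxW, values 0..255),
#'   `thermal_msb` and `thermal_lsb` (HxW each).
#' @export
split_raw_frame <- function(frame) {
  stopifnot(inherits(frame, "raw_frame"))
  h <- frame$height
  w <- frame$width
  n <- h * w
  image_bytes <- frame$payload[seq_len(n)]
  thermal_bytes <- as.integer(frame$payload[n + seq_len(2L * n)])
  msb <- thermal_bytes[seq(1L, 2L * n, by = 2L)]
  lsb <- thermal_bytes[seq(2L, 2L * n, by = 2L)]
  list(
    image_plane = bytes_to_matrix(as.raw(image_bytes), h, w),
    thermal_msb = matrix(msb, nrow = h, ncol = w, byrow = TRUE),
    thermal_lsb = matrix(lsb, nrow = h, ncol = w, byrow = TRUE)
  )
}

#' Decode a thermal byte-pair plane into a calibrated temperature map
#'
#' Reconstructs per-pixel temperature as
#' `gain * ((256*MSB + LSB)/64 - 273.15) + offset` degrees Celsius. With the
#' default calibration (`gain = 1`, `offset = 0`) an all-zero plane decodes to
#' absolute zero.
#'
#' @param thermal_msb,thermal_lsb Integer matrices of most/least significant
#'   bytes (values 0..255), as returned by [split_raw_frame()].
#' @param gain Calibration gain (unitless, > 0).
#' @param offset Calibration offset in degrees Celsius.
#' @return A numeric HxW matrix of temperatures in degrees Celsius with
#'   attributes `gain` and `offset`.
#' @export
decode_temperature_map <- function(thermal_msb, thermal_lsb, gain = 1, offset = 0) {
  if (!is.numeric(gain) || length(gain) != 1 || gain <= 0) {
    stop("calibration gain must be a single positive number", call. = FALSE)
  }
  stopifnot(identical(dim(thermal_msb), dim(thermal_lsb)))
  raw_c <- (256 * thermal_msb + thermal_lsb) / 64 - KELVIN_OFFSET
  map <- gain * raw_c + offset
  attr(map, "gain") <- gain
  attr(map, "offset") <- offset
  map
}

#' Locate the hottest pixel of a temperature map
#'
#' Returns the frame maximum and the 0-based coordinates of the first pixel
#' attaining it (row-major tie-break: smallest y, then smallest x).
#'
#' @param map Numeric temperature matrix.
#' @return A list with `x`, `y` (0-based pixel coordinates) and `t_max`
#'   (degrees Celsius).
#' @export
locate_max_temperature <- function(map) {
  if (is.null(dim(map)) || length(map) == 0) {
    stop("empty temperature map", call. = FALSE)
  }
  t_max <- max(map)
  hits <- which(map == t_max, arr.ind = TRUE)
  # row-major first: order by row (y) then column (x)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  list(x = unname(hits[1, 2] - 1L), y = unname(hits[1, 1] - 1L), t_max = t_max)
}

# Separable 1-D interpolation weights from dst length to src length.
# Half-pixel-center alignment: src = (dst + 0.5) * (n_src/n_dst) - 0.5,
# which reduces to the identity when n_src == n_dst.
interp_weights <- function(n_src, n_dst, method) {
  scale <- n_src / n_dst
  src <- (seq_len(n_dst) - 0.5) * scale - 0.5
  w <- matrix(0, nrow = n_dst, ncol = n_src)
  if (method == "bilinear") {
    i0 <- floor(src)
    fr <- src - i0
    for (j in seq_len(n_dst)) {
      idx <- pmin(pmax(c(i0[j], i0[j] + 1), 0), n_src - 1) + 1
      w[j, idx[1]] <- w[j, idx[1]] + (1 - fr[j])
      w[j, idx[2]] <- w[j, idx[2]] + fr[j]
    }
  } else if (method == "bicubic") {
    # Keys cubic convolution kernel, a = -0.5 (Catmull-Rom)
    kern <- function(s) {
      s <- abs(s)
      ifelse(s <= 1, 1.5 * s^3 - 2.5 * s^2 + 1,
        ifelse(s < 2, -0.5 * s^3 + 2.5 * s^2 - 4 * s + 2, 0)
      )
    }
    i0 <- floor(src)
    for (j in seq_len(n_dst)) {
      taps <- (i0[j] - 1):(i0[j] + 2)
      wt <- kern(src[j] - taps)
      idx <- pmin(pmax(taps, 0), n_src - 1) + 1 # clamp at edges
      for (m in seq_along(taps)) w[j, idx[m]] <- w[j, idx[m]] + wt[m]
    }
  } else {
    stop("unknown interpolation method: ", method, call. = FALSE)
  }
  w
}

#' Resize a temperature map by spatial interpolation
#'
#' Separable bilinear (default) or bicubic interpolation with half-pixel
#' center alignment. Constant maps stay constant and same-size resizing is the
#' identity.
#'
#' @param map Numeric temperature matrix.
#' @param w_out,h_out Target dimensions in pixels (>= 1).
#' @param method `"bilinear"` or `"bicubic"`.
#' @return A numeric `h_out` x `w_out` matrix.
#' @export
resize_temperature_map <- function(map, w_out, h_out, method = c("bilinear", "bicubic")) {
  method <- match.arg(method)
  if (w_out < 1 || h_out < 1) {
    stop("target dimensions must be positive", call. = FALSE)
  }
  h <- nrow(map)
  w <- ncol(map)
  if (h_out == h && w_out == w) {
    return(map)
  }
  wy <- interp_weights(h, h_out, method)
  wx <- interp_weights(w, w_out, method)
  wy %*% unclass(map) %*% t(wx)
}

#' Render a display heatmap from an image plane
#'
#' The visualization branch: contrast scaling (default 1.0, i.e. none), 3x
#' bicubic upscaling, and false-coloring through a colormap. Carries no
#' quantitative role in the pipeline.
#'
#' @param image_plane Integer matrix of display intensities (0..255).
#' @param scale_factor Integer upscaling factor (default 3).
#' @param contrast Linear contrast factor applied before color-mapping
#'   (default 1.0).
#' @param colormap Either a palette name accepted by
#'   [grDevices::hcl.colors()] (default `"inferno"`) or `"gray"` for a
#'   monotone grayscale ramp.
#' @return A numeric array of shape `(3H, 3W, 3)` with RGB values in
#'   \code{[0, 1]}.
#' @export
render_heatmap <- function(image_plane, scale_factor = 3L, contrast = 1.0,
                           colormap = "inferno") {
  stopifnot(is.matrix(image_plane), scale_factor >= 1)
  scaled <- pmin(pmax(contrast * image_plane, 0), 255)
  up <- resize_temperature_map(
    scaled,
    w_out = ncol(image_plane) * scale_factor,
    h_out = nrow(image_plane) * scale_factor,
    method = "bicubic"
  )
  up <- pmin(pmax(up, 0), 255)
  if (identical(colormap, "gray")) {
    lut <- cbind(seq(0, 1, length.out = 256),
                 seq(0, 1, length.out = 256),
                 seq(0, 1, length.out = 256))
  } else {
    cols <- grDevices::hcl.colors(256, palette = colormap)
    lut <- grDevices::col2rgb(cols) / 255
    lut <- t(lut)
  }
  idx <- matrix(as.integer(round(up)) + 1L, nrow = nrow(up))
  out <- array(0, dim = c(nrow(up), ncol(up), 3))
  for (ch in 1:3) out[, , ch] <- matrix(lut[idx, ch], nrow = nrow(up))
  out
}

#' Encode a temperature map and image plane into a raw frame
#'
#' Inverts the decode path: temperatures are de-calibrated, converted to
#' Kelvin * 64 16-bit words (rounded to nearest), and laid out as row-major
#' MSB/LSB pairs after the image plane. Round-tripping through
#' [split_raw_frame()] and [decode_temperature_map()] reproduces the map
#' within the quantization step `gain / 64` Kelvin.
#'
#' @param map Numeric temperature matrix in degrees Celsius.
#' @param image_plane Integer matrix of display intensities (0..255), same
#'   dimensions as `map`.
#' @param gain,offset Calibration used for de-calibration (must match the
#'   decode side).
#' @param frame_index Frame index stored in the resulting [raw_frame()].
#' @return A [raw_frame()].
#' @export
encode_raw_frame <- function(map, image_plane, gain = 1, offset = 0, frame_index = 0L) {
  stopifnot(identical(dim(unclass(map)), dim(image_plane)))
  if (gain <= 0) stop("calibration gain must be positive", call. = FALSE)
  kelvin64 <- round((((unclass(map) - offset) / gain) + KELVIN_OFFSET) * 64)
  if (any(kelvin64 < 0) || any(kelvin64 > 65535)) {
    stop(sprintf(
      "encoding-range error: temperatures map to 16-bit words outside [0, 65535] (range %d..%d)",
      min(kelvin64), max(kelvin64)
    ), call. = FALSE)
  }
  msb <- kelvin64 %/% 256
  lsb <- kelvin64 %% 256
  # interleave MSB/LSB row-major
  msb_rm <- as.integer(t(msb))
  lsb_rm <- as.integer(t(lsb))
  thermal <- integer(2L * length(msb_rm))
  thermal[seq(1L, length(thermal), by = 2L)] <- msb_rm
  thermal[seq(2L, length(thermal), by = 2L)] <- lsb_rm
  payload <- c(matrix_to_bytes(image_plane), as.raw(thermal))
  raw_frame(payload, nrow(map), ncol(map), frame_index)
}

TRF_MAGIC <- charToRaw("TRF1")

#' Write a stream of raw frames to a `.trf` fixture file
#'
#' The `.trf` container is this package's bit-exact raw-frame format: a
#' 16-byte little-endian header (magic `"TRF1"`, height uint16, width uint16,
#' frame rate float32, frame count uint32) followed by each frame's payload
#' (image plane, then thermal MSB/LSB pairs, row-major).
#'
#' @param frames A list of [raw_frame()] objects with identical dimensions.
#' @param path Output file path.
#' @param f_cam Camera frame rate in Hz, stored in the header.
#' @return `path`, invisibly.
#' @export
write_trf <- function(frames, path, f_cam) {
  stopifnot(length(frames) >= 1, f_cam > 0)
  h <- frames[[1]]$height
  w <- frames[[1]]$width
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(TRF_MAGIC, con)
  writeBin(as.integer(c(h, w)), con, size = 2, endian = "little")
  writeBin(as.numeric(f_cam), con, size = 4, endian = "little")
  writeBin(as.integer(length(frames)), con, size = 4, endian = "little")
  for (fr in frames) {
    stopifnot(fr$height == h, fr$width == w)
    writeBin(fr$payload, con)
  }
  invisible(path)
}

#' Read a `.trf` fixture file
#'
#' @param path Path to a file written by [write_trf()].
#' @return A list with `frames` (list of [raw_frame()]), `f_cam`, `height`,
#'   `width`.
#' @export
read_trf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  if (!identical(magic, TRF_MAGIC)) {
    stop("not a .trf file: bad magic", call. = FALSE)
  }
  dims <- readBin(con, "integer", 2, size = 2, endian = "little", signed = FALSE)
  f_cam <- readBin(con, "numeric", 1, size = 4, endian = "little")
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  h <- dims[1]
  w <- dims[2]
  frame_bytes <- 3L * h * w
  frames <- vector("list", n)
  for (k in seq_len(n)) {
    payload <- readBin(con, "raw", frame_bytes)
    if (length(payload) != frame_bytes) {
      stop(sprintf("truncated .trf file: frame %d has %d of %d bytes",
                   k - 1L, length(payload), frame_bytes), call. = FALSE)
    }
    frames[[k]] <- raw_frame(payload, h, w, k - 1L)
  }
  list(frames = frames, f_cam = f_cam, height = h, width = w)
}

#' Export a temperature map as tidy CSV-ready data
#'
#' @param map Numeric temperature matrix.
#' @param frame_index Frame index recorded in the output.
#' @return A tibble with columns `frame_index`, `x`, `y` (0-based), `temp_c`.
#' @export
temperature_map_to_df <- function(map, frame_index = 0L) {
  h <- nrow(map)
  w <- ncol(map)
  tibble::tibble(
    frame_index = as.integer(frame_index),
    x = rep(0:(w - 1), each = h),
    y = rep(0:(h - 1), times = w),
    temp_c = as.vector(unclass(map))
  )
}
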
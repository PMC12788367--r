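# Raw-frame codec: plane splitting, temperature decode/encode, max
# localization, resizing, heatmap rendering, and the .trf container.

test_that("byte pairs decode to the documented temperatures", {
  # hand-evaluated: (256*74 + 222)/64 - 273.15
  msb <- matrix(74L, 1, 1)
  lsb <- matrix(222L, 1, 1)
  expect_equal(decode_temperature_map(msb, lsb)[1, 1], 26.31875)
  expect_equal(decode_temperature_map(msb, lsb, gain = 1.02, offset = -0.5)[1, 1],
               26.345125)
  # all-zero bytes are absolute zero at default calibration
  z <- matrix(0L, 2, 2)
  expect_true(all(decode_temperature_map(z, z) == -273.15))
  expect_error(decode_temperature_map(msb, lsb, gain = 0), "gain")
})

test_that("decode is exactly affine in the calibration", {
  set.seed(41)
  msb <- matrix(sample(0:255, 30, TRUE), 5, 6)
  lsb <- matrix(sample(0:255, 30, TRUE), 5, 6)
  base <- decode_temperature_map(msb, lsb, 1, 0)
  cal <- decode_temperature_map(msb, lsb, gain = 1.07, offset = -2.3)
  expect_equal(as.vector(cal), as.vector(1.07 * unclass(base) - 2.3))
})

test_that("encode/split/decode round-trips within the quantization step", {
  set.seed(42)
  for (dims in list(c(2, 2), c(12, 16), c(7, 9))) {
    map <- random_map(dims[1], dims[2])
    fr <- encode_raw_frame(map, flat_plane(dims[1], dims[2]), frame_index = 3L)
    planes <- split_raw_frame(fr)
    back <- decode_temperature_map(planes$thermal_msb, planes$thermal_lsb)
    expect_lt(max(abs(unclass(back) - map)), 1 / 64 + 1e-12)
    # re-encoding the decoded planes reproduces the payload byte-for-byte
    fr2 <- encode_raw_frame(back, planes$image_plane, frame_index = 3L)
    expect_identical(fr2$payload, fr$payload)
  }
  # calibration-aware round trip: quantization scales with the gain
  map <- random_map(6, 8)
  fr <- encode_raw_frame(map, flat_plane(6, 8), gain = 1.5, offset = -1)
  planes <- split_raw_frame(fr)
  back <- decode_temperature_map(planes$thermal_msb, planes$thermal_lsb,
                                 gain = 1.5, offset = -1)
  expect_lt(max(abs(unclass(back) - map)), 1.5 / 64 + 1e-12)
})

test_that("malformed payloads and out-of-range temperatures are rejected", {
  fr <- encode_raw_frame(random_map(4, 4), flat_plane(4, 4))
  expect_error(raw_frame(fr$payload[-1], 4, 4), "malformed frame.*47.*48")
  expect_error(encode_raw_frame(matrix(-300, 2, 2), flat_plane(2, 2)),
               "encoding-range")
  expect_error(encode_raw_frame(matrix(1e5, 2, 2), flat_plane(2, 2)),
               "encoding-range")
  # all-zero payload decodes to four (0, 0) byte pairs
  planes <- split_raw_frame(raw_frame(raw(12), 2, 2))
  expect_true(all(planes$thermal_msb == 0) && all(planes$thermal_lsb == 0))
})

test_that("locate_max_temperature matches a brute-force scan and tie-breaks row-major", {
  uniform <- matrix(30, 3, 4)
  hit <- locate_max_temperature(uniform)
  expect_equal(c(hit$x, hit$y, hit$t_max), c(0, 0, 30))

  spiked <- matrix(20, 5, 5)
  spiked[3, 4] <- 35 # y = 2, x = 3 (0-based)
  hit <- locate_max_temperature(spiked)
  expect_equal(c(hit$x, hit$y, hit$t_max), c(3, 2, 35))

  set.seed(7)
  for (i in 1:5) {
    map <- random_map(12, 16)
    hit <- locate_max_temperature(map)
    # exhaustive scan oracle
    best <- -Inf; bx <- by <- NA
    for (y in 0:(nrow(map) - 1)) for (x in 0:(ncol(map) - 1)) {
      if (map[y + 1, x + 1] > best) { best <- map[y + 1, x + 1]; bx <- x; by <- y }
    }
    expect_equal(c(hit$x, hit$y, hit$t_max), c(bx, by, best))
  }
  expect_error(locate_max_temperature(matrix(numeric(0), 0, 0)), "empty")
})

test_that("resizing preserves constants, is the identity at same size, and matches hand bilinear", {
  map <- random_map(6, 8, seed = 1)
  expect_equal(resize_temperature_map(map, 8, 6), map)
  const <- matrix(25, 3, 3)
  expect_true(all(abs(resize_temperature_map(const, 7, 5) - 25) < 1e-12))
  expect_true(all(abs(resize_temperature_map(const, 9, 9, "bicubic") - 25) < 1e-12))
  # hand-computed 2x2 -> 4x4 bilinear grid (half-pixel centers, edge clamp)
  m <- matrix(c(1, 3, 2, 4), 2, 2) # [[1,2],[3,4]] by row
  expected <- matrix(c(
    1, 1.25, 1.75, 2,
    1.5, 1.75, 2.25, 2.5,
    2.5, 2.75, 3.25, 3.5,
    3, 3.25, 3.75, 4
  ), 4, 4, byrow = TRUE)
  expect_equal(resize_temperature_map(m, 4, 4), expected)
  expect_error(resize_temperature_map(m, 0, 4), "positive")
})

test_that("heatmap rendering upscales 3x, respects unit contrast, and is monotone", {
  plane <- flat_plane(8, 12, 100L)
  out <- render_heatmap(plane)
  expect_equal(dim(out), c(24, 36, 3))
  # constant plane -> constant color
  expect_equal(length(unique(round(as.vector(out), 10))), 3)
  # full-size check of the documented 3x rule
  expect_equal(dim(render_heatmap(flat_plane(192, 256)))[1:2], c(576, 768))
  # monotone input with a monotone (gray) colormap stays monotone
  ramp <- matrix(as.integer(seq(0, 255, length.out = 16)), 4, 4)
  g <- render_heatmap(ramp, colormap = "gray")
  expect_equal(g[, , 1], g[, , 2])
  row_means <- rowMeans(g[, , 1])
  expect_true(all(diff(row_means) >= -1e-9))
})

test_that(".trf files round-trip frames, dimensions and frame rate", {
  set.seed(9)
  frames <- lapply(0:4, function(k) {
    encode_raw_frame(random_map(6, 8), flat_plane(6, 8), frame_index = k)
  })
  path <- withr::local_tempfile(fileext = ".trf")
  write_trf(frames, path, f_cam = 25)
  back <- read_trf(path)
  expect_equal(back$f_cam, 25)
  expect_equal(back$height, 6)
  expect_equal(back$width, 8)
  expect_length(back$frames, 5)
  for (k in 1:5) expect_identical(back$frames[[k]]$payload, frames[[k]]$payload)
  expect_error(read_trf(withr::local_tempfile(lines = "not a trf")), "magic")
})
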
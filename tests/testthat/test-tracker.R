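# Constant-velocity Kalman tracker: measurement conversions, predict/update
# algebra, structural properties of (F, H), and end-to-end tracking.

test_that("box/measurement conversions follow the center-size convention", {
  expect_equal(bbox_to_measurement(c(0, 0, 10, 20)), c(5, 10, 10, 20))
  expect_equal(bbox_to_measurement(detection(10, 10, 30, 50)), c(20, 30, 20, 40))
  # degenerate box is accepted
  expect_equal(bbox_to_measurement(c(2, 3, 2, 3)), c(2, 3, 0, 0))
  expect_error(bbox_to_measurement(c(5, 5, 2, 2)), "inverted")

  cfg <- kalman_config(25)
  st <- track_init(cfg, z = c(5, 10, 10, 20))
  expect_equal(state_to_bbox(st), c(0, 0, 10, 20))
  # round trip state -> box -> measurement
  st2 <- track_init(cfg, z = c(33.5, 21, 7, 9))
  expect_equal(bbox_to_measurement(state_to_bbox(st2)), c(33.5, 21, 7, 9))
  # zero-size state gives a single-point box
  st3 <- track_init(cfg, z = c(4, 4, 0, 0))
  expect_equal(state_to_bbox(st3), c(4, 4, 4, 4))
})

test_that("prediction advances positions by velocity*dt and inflates P", {
  cfg <- kalman_config(25) # dt = 0.04
  st <- track_init(cfg, z = c(10, 10, 5, 5))
  st$x[5] <- 25 # cx velocity 25 px/s
  pred <- kf_predict(st, cfg)
  expect_equal(pred$x[1], 11) # 25 px/s * 0.04 s = 1 px
  expect_equal(pred$x[2:4], c(10, 5, 5))
  expect_equal(pred$x[5:8], c(25, 0, 0, 0))
  expect_gte(sum(diag(pred$P)), sum(diag(st$P)))
  expect_error(kf_predict(track_init(cfg), cfg), "not initialized")
})

test_that("the update step matches a literal matrix-arithmetic oracle", {
  # independent oracle: innovation/gain/posterior relations written out
  # directly from their definitions
  oracle_update <- function(x, P, z, H, R) {
    y <- z - H %*% x
    S <- H %*% P %*% t(H) + R
    K <- P %*% t(H) %*% solve(S)
    list(
      x = as.numeric(x + K %*% y),
      P = (diag(8) - K %*% H) %*% P
    )
  }
  set.seed(23)
  cfg <- kalman_config(25, q_scale = 0.7, r_scale = 2.5)
  for (i in 1:20) {
    st <- track_init(cfg, z = runif(4, 0, 50))
    st$x[5:8] <- rnorm(4, 0, 5)
    A <- matrix(rnorm(64, sd = 0.5), 8, 8)
    st$P <- A %*% t(A) + diag(8) # random SPD covariance
    z <- runif(4, 0, 50)
    got <- kf_update(st, z, cfg)
    want <- oracle_update(st$x, st$P, z, cfg$H, cfg$R)
    expect_equal(got$x, want$x, tolerance = 1e-10)
    expect_equal(got$P, (want$P + t(want$P)) / 2, tolerance = 1e-10)
  }
})

test_that("zero innovation leaves the state unchanged and tiny R snaps to z", {
  cfg <- kalman_config(25)
  st <- track_init(cfg, z = c(10, 20, 6, 8))
  same <- kf_update(st, c(10, 20, 6, 8), cfg)
  expect_equal(same$x, st$x)
  tiny_r <- kalman_config(25, r_scale = 1e-12)
  st2 <- track_init(tiny_r, z = c(10, 20, 6, 8))
  snapped <- kf_update(st2, c(14, 22, 7, 9), tiny_r)
  expect_equal(snapped$x[1:4], c(14, 22, 7, 9), tolerance = 1e-6)
})

test_that("(F, H) is observable with rank 8 and F has all eigenvalues 1", {
  for (f_cam in c(10, 25, 60)) {
    cfg <- kalman_config(f_cam)
    obs <- do.call(rbind, lapply(0:3, function(p) {
      cfg$H %*% (if (p == 0) diag(8) else Reduce(`%*%`, rep(list(cfg$F), p)))
    }))
    expect_equal(qr(obs)$rank, 8)
    expect_equal(sort(Mod(eigen(cfg$F, only.values = TRUE)$values)), rep(1, 8))
  }
})

test_that("P stays symmetric positive semi-definite across many random steps", {
  set.seed(31)
  cfg <- kalman_config(25)
  st <- track_init(cfg, z = c(30, 30, 10, 10))
  for (i in 1:10000) {
    st <- kf_predict(st, cfg)
    if (i %% 2 == 0) st <- kf_update(st, runif(4, 0, 60), cfg)
  }
  expect_equal(st$P, t(st$P))
  expect_gte(min(eigen(st$P, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("velocities of a linearly moving box are recovered within 1%", {
  cfg <- kalman_config(25, q_scale = 1, r_scale = 1e-6)
  vel <- c(12, -8, 1.5, -0.5) # px/s truth
  z0 <- c(50, 60, 20, 24)
  st <- track_init(cfg, z = z0)
  for (k in 1:50) {
    st <- kf_predict(st, cfg)
    st <- kf_update(st, z0 + vel * k * cfg$dt, cfg)
  }
  expect_lt(max(abs(st$x[5:8] - vel) / abs(vel)), 0.01)
})

test_that("track_step gates updates to scheduled frames and coasts through dropouts", {
  f_cam <- 25
  cfg <- kalman_config(f_cam, q_scale = 1e-9, r_scale = 1e-9)
  vel <- c(10, 5, 0, 0)
  truth_box <- function(k) {
    c(20, 20, 30, 32) + c(vel[1], vel[2], vel[1], vel[2]) * k / f_cam
  }
  st <- track_init(cfg)
  # first step before any detection: no-track condition
  nores <- track_step(st, 0, NULL, cfg)
  expect_null(nores$roi)
  # constant-velocity truth with a noiseless oracle on scheduled frames
  rois <- list()
  for (k in 0:120) {
    det <- if (k %% 2 == 0) do.call(detection, as.list(truth_box(k))) else NULL
    res <- track_step(st, k, det, cfg)
    st <- res$state
    rois[[k + 1]] <- res$roi
    # a detection on an odd frame must not update
    if (k %% 2 == 1) expect_equal(res$m_k, 0L)
  }
  # after burn-in the tracked ROI follows the truth closely on all frames
  errs <- vapply(60:120, function(k) max(abs(rois[[k + 1]] - truth_box(k))),
                 numeric(1))
  expect_lt(max(errs), 1e-3)

  # withhold detections: the box coasts along the last velocity estimate
  st_coast <- st
  base_roi <- rois[[121]]
  for (j in 1:10) {
    res <- track_step(st_coast, 120 + j, NULL, cfg)
    st_coast <- res$state
    expected <- base_roi + c(vel[1], vel[2], vel[1], vel[2]) * j / f_cam
    expect_equal(res$roi, expected, tolerance = 1e-2)
  }

  # beyond max_coast_frames the track is dropped, then re-initializes
  cfg_short <- kalman_config(f_cam, max_coast_frames = 5)
  st2 <- track_init(cfg_short, z = c(10, 10, 4, 4))
  dropped <- FALSE
  for (j in 1:8) {
    res <- track_step(st2, j, NULL, cfg_short)
    st2 <- res$state
    if (is.null(res$roi)) dropped <- TRUE
  }
  expect_true(dropped)
  expect_false(st2$initialized)
  reinit <- track_step(st2, 10, detection(40, 40, 50, 50), cfg_short)
  expect_true(reinit$state$initialized)
  expect_equal(reinit$roi, c(40, 40, 50, 50))
})
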
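test_that("tip localization picks the configured end of a horizontal band", {
  mask <- matrix(FALSE, 480, 640)
  mask[235:245, 100:300] <- TRUE
  mid <- line2d(m = 0, b = 240)
  det <- detector_config(tip_offset_px = 0)
  tip <- locate_tip(mask, mid, det)
  expect_true(tip$valid)
  # horizontal band: y tie broken toward the left (bottom-left convention)
  expect_equal(tip$x, 100, tolerance = 1.1)
  expect_equal(tip$y, 240, tolerance = 1.1)

  det_min <- detector_config(tip_offset_px = 0, tip_rule = "min_y")
  tip2 <- locate_tip(mask, mid, det_min)
  expect_equal(tip2$x, 300, tolerance = 1.1)
})

test_that("tip localization honors the tip offset along the midline", {
  mask <- matrix(FALSE, 480, 640)
  mask[235:245, 100:300] <- TRUE
  mid <- line2d(m = 0, b = 240)
  tip <- locate_tip(mask, mid, detector_config(tip_offset_px = 18))
  expect_equal(tip$x, 100 - 18, tolerance = 1.1)
})

test_that("tip estimate on rendered frames lands within 2 px of the truth", {
  cfg <- scene_config(
    trajectory = data.frame(x = 320, y = 340, yaw_deg = 90),
    seed = 8
  )
  det <- scene_detector(cfg)
  d <- detect_frame(render_frame(cfg, 1), det)
  tip <- locate_tip(d$mask, d$midline, det)
  expect_true(tip$valid)
  expect_lt(abs(tip$x - 320), 2)
  expect_lt(abs(tip$y - 340), 2)
})

test_that("an empty mask yields no detection", {
  tip <- locate_tip(matrix(FALSE, 480, 640), line2d(m = 0, b = 240),
                    detector_config())
  expect_false(tip$valid)
})

test_that("prediction follows the constant-velocity model", {
  cfg <- track_config(Q = diag(0, 4))
  tr <- kf_create(0, 0, 1, 2, cfg)
  tr <- kf_predict(tr)
  expect_equal(unname(tr$state), c(1, 2, 1, 2))

  # static target with no velocity uncertainty and Q = 0: nothing moves
  P_static <- diag(c(4, 4, 0, 0))
  static <- kf_predict(kf_create(5, 7, 0, 0, cfg, P = P_static))
  expect_equal(unname(static$state), c(5, 7, 0, 0))
  expect_equal(static$P, P_static)
  # positive process noise strictly inflates the covariance trace
  cfgQ <- track_config()
  withQ <- kf_predict(kf_create(5, 7, 0, 0, cfgQ, P = P_static))
  expect_gt(sum(diag(withQ$P)), sum(diag(P_static)))
})

test_that("update interpolates between prediction and measurement", {
  cfg0 <- track_config(R_m = diag(1e-12, 2))
  tr <- kf_predict(kf_create(10, 10, 0, 0, cfg0))
  tr <- kf_update(tr, c(20, 30))
  expect_equal(tr$state[["x"]], 20, tolerance = 1e-6)
  expect_equal(tr$state[["y"]], 30, tolerance = 1e-6)

  cfgInf <- track_config(R_m = diag(1e12, 2))
  tr2 <- kf_predict(kf_create(10, 10, 0, 0, cfgInf))
  tr2 <- kf_update(tr2, c(20, 30))
  expect_equal(tr2$state[["x"]], 10, tolerance = 1e-6)
  expect_equal(tr2$state[["y"]], 10, tolerance = 1e-6)
})

test_that("filtering a static target beats the raw measurements", {
  set.seed(42)
  n <- 100
  z <- cbind(rnorm(n, 50, 3), rnorm(n, 80, 3))
  cfg <- track_config(R_m = diag(9, 2), Q = diag(c(0.001, 0.001, 0.001, 0.001)))
  tr <- kf_create(z[1, 1], z[1, 2], 0, 0, cfg)
  est <- matrix(0, n, 2)
  est[1, ] <- z[1, ]
  for (i in 2:n) {
    tr <- kf_predict(tr)
    tr <- kf_update(tr, z[i, ])
    est[i, ] <- tr$state[1:2]
  }
  rmse_est <- sqrt(mean((est[, 1] - 50)^2 + (est[, 2] - 80)^2))
  rmse_meas <- sqrt(mean((z[, 1] - 50)^2 + (z[, 2] - 80)^2))
  expect_lt(rmse_est, rmse_meas)
})

test_that("covariance stays symmetric positive-definite over 1000 cycles", {
  set.seed(3)
  tr <- kf_create(0, 0, 1, 1)
  for (i in 1:1000) {
    tr <- kf_predict(tr)
    tr <- kf_update(tr, c(i + rnorm(1, 0, 2), i + rnorm(1, 0, 2)))
  }
  expect_equal(tr$P, t(tr$P))
  expect_gt(min(eigen(tr$P, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("noise-free linear detections pass through unchanged", {
  n <- 40
  det <- data.frame(
    frame = 1:n, valid = TRUE,
    x = 100 + 2 * (1:n), y = 200 + 1 * (1:n), yaw_deg = 60
  )
  out <- track_sequence(det)
  expect_equal(nrow(out), n)
  expect_lt(max(abs(out$x - det$x)), 0.5)
  expect_lt(max(abs(out$y - det$y)), 0.5)
  expect_true(all(out$source == "detected"))
})

test_that("the track coasts through an occlusion gap at constant velocity", {
  n <- 60
  truth_x <- 100 + 2 * (1:n)
  truth_y <- 200 + 1.5 * (1:n)
  set.seed(11)
  det <- data.frame(
    frame = 1:n, valid = TRUE,
    x = truth_x + rnorm(n, 0, 0.5), y = truth_y + rnorm(n, 0, 0.5),
    yaw_deg = 60
  )
  gap <- 30:39
  det$valid[gap] <- FALSE
  out <- track_sequence(det)
  coast <- out[out$frame %in% gap, ]
  expect_equal(nrow(coast), 10)
  expect_true(all(coast$source == "predicted"))
  expect_lt(max(abs(coast$x - truth_x[gap])), 3)
  expect_lt(max(abs(coast$y - truth_y[gap])), 3)
})

test_that("coasting stops after max_coast consecutive misses", {
  n <- 50
  det <- data.frame(frame = 1:n, valid = FALSE, x = NA_real_, y = NA_real_)
  det[1:2, c("valid", "x", "y")] <- list(TRUE, c(100, 102), c(200, 201))
  cfg <- track_config(max_coast = 5)
  out <- track_sequence(det, cfg)
  expect_equal(max(out$frame), 2 + 5)
  expect_equal(sum(out$source == "predicted"), 5)

  # all-miss input yields an empty track
  none <- data.frame(frame = 1:10, valid = FALSE, x = NA_real_, y = NA_real_)
  expect_equal(nrow(track_sequence(none)), 0)
})

test_that("smoothing does not degrade constant-velocity tracking", {
  worse <- 0
  for (seed in 1:5) {
    set.seed(seed)
    n <- 120
    tx <- 50 + 3 * (1:n)
    ty <- 400 - 2 * (1:n)
    det <- data.frame(
      frame = 1:n, valid = TRUE,
      x = tx + rnorm(n, 0, 2), y = ty + rnorm(n, 0, 2), yaw_deg = 60
    )
    out <- track_sequence(det)
    rmse_raw <- sqrt(mean((det$x - tx)^2 + (det$y - ty)^2))
    m <- match(out$frame, det$frame)
    rmse_kf <- sqrt(mean((out$x - tx[m])^2 + (out$y - ty[m])^2))
    if (rmse_kf > rmse_raw) worse <- worse + 1
  }
  expect_equal(worse, 0)
})
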
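test_that("preprocessing resizes to the working resolution", {
  big <- array(runif(108 * 192 * 3), dim = c(108, 192, 3))
  big_hd <- resize_frame(big, 1920, 1080) # stand-in for a camera frame
  expect_equal(dim(big_hd), c(1080, 1920, 3))
  out <- preprocess_frame(big_hd)
  expect_equal(dim(out), c(480, 640, 3))
  # already-640x480 input keeps its size
  small <- array(runif(480 * 640 * 3), dim = c(480, 640, 3))
  expect_equal(dim(preprocess_frame(small)), c(480, 640, 3))
  expect_error(preprocess_frame(matrix(0, 10, 10)), "3-channel")
})

test_that("blurring a constant frame returns it unchanged", {
  const <- array(0.4, dim = c(480, 640, 3))
  expect_equal(preprocess_frame(const), const, tolerance = 1e-12)
})

test_that("RGB to HSV conversion matches the hexcone primaries", {
  px <- function(r, g, b) {
    f <- array(0, dim = c(1, 1, 3))
    f[1, 1, ] <- c(r, g, b)
    rgb_to_hsv_frame(f)[1, 1, ]
  }
  expect_equal(px(1, 0, 0), c(0, 1, 1))
  expect_equal(px(0, 1, 0), c(120, 1, 1))
  expect_equal(px(0, 1, 1), c(180, 1, 1))
  expect_equal(px(255, 0, 0), c(0, 1, 1)) # 0-255 input scale
})

test_that("segmentation covers the rendered band and rejects other colors", {
  cfg <- small_scene(1)
  det <- scene_detector(cfg)
  pre <- preprocess_frame(render_frame(cfg, 1), det)
  hsv <- rgb_to_hsv_frame(pre)
  mask <- segment_marker(hsv, det$range, det)
  interior <- band_interior_mask(cfg, 1, shrink = 3)
  expect_gt(mean(mask[interior]), 0.95)

  red <- array(0, dim = c(480, 640, 3))
  red[, , 1] <- 1
  hsv_red <- rgb_to_hsv_frame(red)
  expect_false(any(segment_marker(hsv_red, det$range, det)))
})

test_that("erosion removes isolated hot pixels", {
  red <- array(0, dim = c(480, 640, 3))
  red[, , 1] <- 1
  red[240, 320, ] <- c(0, 1, 0) # one marker-colored pixel
  mask <- segment_marker(rgb_to_hsv_frame(red), default_marker_range())
  expect_false(any(mask))
})

test_that("segmentation is invariant to illumination gain within value bounds", {
  cfg <- small_scene(1, noise_sd = 0)
  det <- scene_detector(cfg)
  f <- render_frame(cfg, 1)
  m1 <- segment_marker(rgb_to_hsv_frame(preprocess_frame(f, det)), det$range, det)
  m2 <- segment_marker(
    rgb_to_hsv_frame(preprocess_frame(f * 0.7, det)), det$range, det
  )
  expect_gt(sum(m1 & m2) / sum(m1 | m2), 0.95)
})

test_that("morphological opening shrinks and closing grows the mask", {
  set.seed(5)
  mask <- matrix(runif(100 * 100) > 0.6, 100, 100)
  kern <- EBImage::makeBrush(5, "disc")
  opened <- EBImage::dilate(EBImage::erode(mask * 1, kern), kern) > 0.5
  closed <- EBImage::erode(EBImage::dilate(mask * 1, kern), kern) > 0.5
  expect_lte(sum(opened), sum(mask))
  expect_gte(sum(closed), sum(mask))
})

test_that("the largest contour is selected with a deterministic tie-break", {
  m <- matrix(FALSE, 100, 100)
  m[10:29, 10:29] <- TRUE # 400 px^2
  m[60:69, 60:68] <- TRUE # 90 px^2
  ct <- select_contour(m, min_area = 50)
  expect_equal(ct$area, 400)
  expect_equal(ct$bbox, c(10, 29, 10, 29))

  expect_null(select_contour(matrix(FALSE, 10, 10)))
  expect_null(select_contour(m, min_area = 1000))

  # equal areas: smaller (row, col) of the bounding-box top-left corner wins
  t1 <- matrix(FALSE, 100, 100)
  t1[40:49, 70:79] <- TRUE
  t1[40:49, 10:19] <- TRUE
  expect_equal(select_contour(t1, 10)$bbox[3], 10)
  t2 <- matrix(FALSE, 100, 100)
  t2[60:69, 30:39] <- TRUE
  t2[20:29, 30:39] <- TRUE
  expect_equal(select_contour(t2, 10)$bbox[1], 20)
})

test_that("probe edges are recovered for known rectangles", {
  m <- matrix(FALSE, 480, 640)
  m[100:129, 200:399] <- TRUE
  e <- probe_edges(m, select_contour(m, 200))
  expect_length(e, 2)
  expect_lt(abs(e[[1]]$m), 0.01)
  expect_lt(abs(e[[2]]$m), 0.01)
  sep <- abs(e[[1]]$b - e[[2]]$b)
  expect_equal(sep, 29, tolerance = 2) # boundary rows 100 and 129

  # rectangle at 45 degrees
  X <- matrix(rep(1:640, each = 480), 480)
  Y <- matrix(rep(1:480, 640), 480)
  u <- c(cos(pi / 4), -sin(pi / 4))
  nn <- c(-u[2], u[1])
  ax <- (X - 150) * u[1] + (Y - 350) * u[2]
  pp <- (X - 150) * nn[1] + (Y - 350) * nn[2]
  m45 <- ax >= 0 & ax <= 200 & abs(pp) <= 15
  e45 <- probe_edges(m45, select_contour(m45, 200))
  expect_length(e45, 2)
  for (ln in e45) {
    expect_lt(abs(abs(atan(ln$m) * 180 / pi) - 45), 1)
  }
})

test_that("a circular blob yields no straight edge pair", {
  X <- matrix(rep(1:640, each = 480), 480)
  Y <- matrix(rep(1:480, 640), 480)
  circ <- (X - 320)^2 + (Y - 240)^2 <= 40^2
  expect_null(probe_edges(circ, select_contour(circ, 200)))
})

test_that("the midline bisects the edge pair", {
  mid <- midline(list(line2d(m = 1, b = 0), line2d(m = 1, b = 10)))
  expect_equal(mid$m, 1, tolerance = 1e-9)
  expect_equal(mid$b, 5, tolerance = 1e-9)

  same <- midline(list(line2d(m = -0.5, b = 3), line2d(m = -0.5, b = 3)))
  expect_equal(same$m, -0.5, tolerance = 1e-9)
  expect_equal(same$b, 3, tolerance = 1e-9)

  vert <- midline(list(
    line2d(vertical = TRUE, x0 = 10),
    line2d(vertical = TRUE, x0 = 20)
  ))
  expect_true(vert$vertical)
  expect_equal(vert$x0, 15)

  expect_error(
    midline(list(line2d(m = 0, b = 0), line2d(m = 1, b = 0))),
    "near-parallel"
  )
})

test_that("end-to-end detection tracks the commanded yaw across orientations", {
  for (yaw in c(30, 75, 90, 140)) {
    cfg <- scene_config(
      trajectory = data.frame(x = 300, y = 350, yaw_deg = yaw),
      seed = 3
    )
    det <- scene_detector(cfg)
    d <- detect_frame(render_frame(cfg, 1), det)
    expect_true(d$valid)
    tip <- locate_tip(d$mask, d$midline, det)
    err <- abs(tip$yaw_deg - yaw)
    expect_lt(min(err, 180 - err), 2)
  }
})
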
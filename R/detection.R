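#' HSV threshold band
#'
#' @param hue_lo,hue_hi hue bounds in degrees `[0, 360)`; the band may wrap
#'   through 360 (`hue_lo > hue_hi`).
#' @param sat_lo,sat_hi,val_lo,val_hi saturation and value bounds in `[0, 1]`.
#' @return object of class `hsv_range`.
#' @export
hsv_range <- function(hue_lo, hue_hi, sat_lo = 0.35, sat_hi = 1,
                      val_lo = 0.25, val_hi = 1) {
  stopifnot(
    hue_lo >= 0, hue_lo < 360, hue_hi >= 0, hue_hi < 360,
    sat_lo <= sat_hi, val_lo <= val_hi
  )
  structure(
    list(
      hue_lo = hue_lo, hue_hi = hue_hi,
      sat_lo = sat_lo, sat_hi = sat_hi,
      val_lo = val_lo, val_hi = val_hi
    ),
    class = "hsv_range"
  )
}

#' Default marker color bands
#'
#' Green brackets pure green (120 deg), cyan brackets pure cyan (180 deg),
#' both with margin against tissue hues (yellow through purple).
#'
#' @param color `"green"` or `"cyan"`.
#' @return an [hsv_range()].
#' @export
default_marker_range <- function(color = c("green", "cyan")) {
  color <- match.arg(color)
  switch(color,
    green = hsv_range(90, 150),
    cyan = hsv_range(160, 200)
  )
}

#' Detector configuration
#'
#' @param marker_color marker color preset, used when `range` is `NULL`.
#' @param range an [hsv_range()] overriding the preset.
#' @param blur_size,blur_sigma Gaussian pre-blur (11 px kernel, sigma 2).
#' @param morph_size diameter of the elliptical structuring element (5 px).
#' @param n_erode,n_dilate morphology repetitions (2 erosions, then 2
#'   dilations).
#' @param min_area smallest acceptable contour area in px^2 at 640 x 480.
#' @param theta_step_deg,rho_step_px Hough accumulator resolution.
#' @param parallel_tol_deg maximum angle between the two probe edges.
#' @param width_range_px acceptable perpendicular separation of the edge
#'   pair, in pixels.
#' @param band_px_range optional `c(min, max)` acceptable marker band length
#'   along the midline; detections outside it are rejected (used to reject
#'   partially occluded markers when the expected band length is known).
#' @param tip_rule which midline endpoint is the tip: `"max_y"` (probe
#'   descends into the frame from the top; the tip is the lower end) or
#'   `"min_y"`.
#' @param tip_offset_px distance from the marker band end to the physical tip
#'   along the midline, in pixels.
#' @return object of class `detector_config`.
#' @export
detector_config <- function(marker_color = "green", range = NULL,
                            blur_size = 11, blur_sigma = 2,
                            morph_size = 5, n_erode = 2, n_dilate = 2,
                            min_area = 200,
                            theta_step_deg = 1, rho_step_px = 1,
                            parallel_tol_deg = 5,
                            width_range_px = c(5, 150),
                            band_px_range = NULL,
                            tip_rule = c("max_y", "min_y"),
                            tip_offset_px = 0) {
  tip_rule <- match.arg(tip_rule)
  if (is.null(range)) range <- default_marker_range(marker_color)
  structure(
    list(
      range = range,
      blur_size = blur_size, blur_sigma = blur_sigma,
      morph_size = morph_size, n_erode = n_erode, n_dilate = n_dilate,
      min_area = min_area,
      theta_step_deg = theta_step_deg, rho_step_px = rho_step_px,
      parallel_tol_deg = parallel_tol_deg,
      width_range_px = width_range_px,
      band_px_range = band_px_range,
      tip_rule = tip_rule,
      tip_offset_px = tip_offset_px
    ),
    class = "detector_config"
  )
}

#' Preprocess a video frame for detection
#'
#' Resizes to the working resolution of 640 x 480 (direct resize, aspect not
#' preserved) and applies a Gaussian blur that suppresses high spatial
#' frequencies while keeping the flat-textured probe visible.
#'
#' @param frame RGB array `c(h, w, 3)`.
#' @param config a [detector_config()].
#' @return blurred 480 x 640 x 3 array.
#' @export
preprocess_frame <- function(frame, config = detector_config()) {
  d <- dim(frame)
  if (length(d) != 3 || d[3] != 3) stop("frame must be a 3-channel RGB image")
  frame <- resize_frame(frame, width = 640, height = 480)
  blur_frame(frame, size = config$blur_size, sigma = config$blur_sigma)
}

#' Threshold an HSV frame into a marker mask
#'
#' A pixel passes when hue, saturation and value all lie within the band
#' (hue wrap-around honored); morphological erosions then dilations with an
#' elliptical element remove impulsive noise and close small gaps.
#'
#' @param hsv HSV array from [rgb_to_hsv_frame()].
#' @param range an [hsv_range()].
#' @param config a [detector_config()] (morphology settings).
#' @return logical matrix mask.
#' @export
segment_marker <- function(hsv, range = default_marker_range(),
                           config = detector_config()) {
  h <- hsv[, , 1]
  s <- hsv[, , 2]
  v <- hsv[, , 3]
  hue_ok <- if (range$hue_lo <= range$hue_hi) {
    h >= range$hue_lo & h <= range$hue_hi
  } else {
    h >= range$hue_lo | h <= range$hue_hi
  }
  mask <- hue_ok & s >= range$sat_lo & s <= range$sat_hi &
    v >= range$val_lo & v <= range$val_hi
  m <- mask * 1
  if (config$morph_size > 1 && (config$n_erode > 0 || config$n_dilate > 0)) {
    kern <- EBImage::makeBrush(config$morph_size, shape = "disc")
    for (i in seq_len(config$n_erode)) m <- EBImage::erode(m, kern)
    for (i in seq_len(config$n_dilate)) m <- EBImage::dilate(m, kern)
  }
  m > 0.5
}

#' Select the largest connected component of a mask
#'
#' Components are ranked by pixel area; the largest is retained as the
#' marker.  Exact ties go to the component whose bounding-box top-left corner
#' has the smaller row, then column.
#'
#' @param mask logical matrix.
#' @param min_area components smaller than this are rejected.
#' @return `NULL`, or a list with `pixels` (n x 2 matrix of row, col),
#'   `area` (px^2) and `bbox` (`r0, r1, c0, c1`).
#' @export
select_contour <- function(mask, min_area = 200) {
  if (!any(mask)) {
    return(NULL)
  }
  lab <- EBImage::bwlabel(mask * 1)
  areas <- tabulate(as.integer(lab[lab > 0]))
  best_area <- max(areas)
  if (best_area < min_area) {
    return(NULL)
  }
  cand <- which(areas == best_area)
  if (length(cand) > 1) {
    corners <- t(vapply(cand, function(l) {
      px <- which(lab == l, arr.ind = TRUE)
      c(min(px[, 1]), min(px[, 2]))
    }, numeric(2)))
    cand <- cand[order(corners[, 1], corners[, 2])]
  }
  px <- which(lab == cand[1], arr.ind = TRUE)
  list(
    pixels = px,
    area = best_area,
    bbox = c(min(px[, 1]), max(px[, 1]), min(px[, 2]), max(px[, 2]))
  )
}

#' A 2-D line in slope-intercept or vertical form
#'
#' Exactly one representation is active: `y = m x + b`, or the vertical line
#' `x = x0`.  The normal form (`theta` in degrees `[0, 180)`, signed `rho` in
#' px, with `x cos(theta) + y sin(theta) = rho`) is kept as attributes.
#'
#' @param m,b slope and intercept.
#' @param vertical logical; when `TRUE`, `x0` is used instead of `(m, b)`.
#' @param x0 x-intercept of a vertical line.
#' @return object of class `line2d`.
#' @export
line2d <- function(m = NULL, b = NULL, vertical = FALSE, x0 = NULL) {
  if (vertical) {
    stopifnot(!is.null(x0))
    out <- structure(
      list(m = NA_real_, b = NA_real_, vertical = TRUE, x0 = x0),
      class = "line2d"
    )
    attr(out, "theta") <- 0
    attr(out, "rho") <- unname(x0)
  } else {
    stopifnot(!is.null(m), !is.null(b))
    out <- structure(
      list(m = m, b = b, vertical = FALSE, x0 = NA_real_),
      class = "line2d"
    )
    # normal (cos t, sin t) with positive y-component: t = atan2(1, -m)
    nrm <- sqrt(1 + m^2)
    attr(out, "theta") <- unname(atan2(1, -m) * 180 / pi)
    attr(out, "rho") <- unname(b / nrm)
  }
  out
}

#' @export
print.line2d <- function(x, ...) {
  if (x$vertical) {
    cat(sprintf("<line2d: x = %.3f>\n", x$x0))
  } else {
    cat(sprintf("<line2d: y = %.4f x + %.3f>\n", x$m, x$b))
  }
  invisible(x)
}

line_from_theta_rho <- function(theta_deg, rho) {
  theta_deg <- unname(theta_deg) %% 360
  rho <- unname(rho)
  if (theta_deg >= 180) {
    theta_deg <- theta_deg - 180
    rho <- -rho
  }
  t <- theta_deg * pi / 180
  if (abs(sin(t)) < 1e-8) {
    line2d(vertical = TRUE, x0 = rho / cos(t))
  } else {
    line2d(m = -cos(t) / sin(t), b = rho / sin(t))
  }
}

line_theta_rho <- function(line) {
  c(theta = attr(line, "theta"), rho = attr(line, "rho"))
}

ang_dist_180 <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Hough transform over line normal angles [0, 180); returns peaks as
# data.frame(theta, rho, count), sub-bin refined by local centroid.
hough_peaks <- function(xy, theta_step = 1, rho_step = 1, n_peaks = 8,
                        suppress_theta = 10, suppress_rho = 8) {
  thetas <- seq(0, 180 - theta_step, by = theta_step)
  tr <- thetas * pi / 180
  rho <- outer(xy[, 1], cos(tr)) + outer(xy[, 2], sin(tr))
  rmax <- max(abs(rho)) + rho_step
  ri <- round((rho + rmax) / rho_step) + 1
  n_rho <- max(ri)
  acc <- matrix(0L, n_rho, length(thetas))
  idx <- as.vector(ri + (col(ri) - 1L) * n_rho)
  tab <- tabulate(idx, nbins = n_rho * length(thetas))
  acc[] <- tab
  peaks <- data.frame(theta = numeric(0), rho = numeric(0), count = numeric(0))
  for (p in seq_len(n_peaks)) {
    m <- which.max(acc)
    cnt <- acc[m]
    if (cnt <= 0) break
    pr <- (m - 1) %% n_rho + 1
    pt <- (m - 1) %/% n_rho + 1
    # sub-bin refinement: centroid over the 3x3 neighborhood
    rr <- pmax(1, pr - 1):pmin(n_rho, pr + 1)
    tt <- pmax(1, pt - 1):pmin(length(thetas), pt + 1)
    w <- acc[rr, tt, drop = FALSE]
    ws <- sum(w)
    rho_hat <- sum(outer(rr, rep(1, length(tt))) * w) / ws
    th_hat <- sum(outer(rep(1, length(rr)), tt) * w) / ws
    peaks <- rbind(peaks, data.frame(
      theta = (th_hat - 1) * theta_step,
      rho = (rho_hat - 1) * rho_step - rmax,
      count = cnt
    ))
    # non-maximum suppression around the peak (theta wraps mod 180)
    rho_vals <- (seq_len(n_rho) - 1) * rho_step - rmax
    rho_peak <- rho_vals[pr]
    near <- which(ang_dist_180(thetas, thetas[pt]) <= suppress_theta)
    for (tc in near) {
      target <- if (abs(thetas[tc] - thetas[pt]) > 90) -rho_peak else rho_peak
      rs <- which(abs(rho_vals - target) <= suppress_rho)
      if (length(rs) > 0) acc[rs, tc] <- 0L
    }
  }
  peaks
}

#' Detect the two probe edge lines
#'
#' The mask boundary inside the contour's bounding box feeds a Hough
#' transform; the strongest peak and the strongest sufficiently supported
#' near-parallel peak whose perpendicular separation is consistent with the
#' marker width are returned as the probe edges.
#'
#' @param mask logical mask from [segment_marker()].
#' @param contour result of [select_contour()].
#' @param config a [detector_config()].
#' @return list of two [line2d()] edges (strongest first), or `NULL` when no
#'   qualifying near-parallel pair exists.
#' @export
probe_edges <- function(mask, contour, config = detector_config()) {
  if (is.null(contour)) {
    return(NULL)
  }
  bb <- contour$bbox
  r0 <- max(1, bb[1] - 3)
  r1 <- min(nrow(mask), bb[2] + 3)
  c0 <- max(1, bb[3] - 3)
  c1 <- min(ncol(mask), bb[4] + 3)
  sub <- mask[r0:r1, c0:c1]
  kern <- EBImage::makeBrush(3, shape = "box")
  inner <- EBImage::erode(sub * 1, kern) > 0.5
  edge <- sub & !inner
  pix <- which(edge, arr.ind = TRUE)
  if (nrow(pix) < 10) {
    return(NULL)
  }
  xy <- cbind(pix[, 2] + c0 - 1, pix[, 1] + r0 - 1) # (x, y) full-frame
  peaks <- hough_peaks(
    xy,
    theta_step = config$theta_step_deg,
    rho_step = config$rho_step_px
  )
  if (nrow(peaks) < 2) {
    return(NULL)
  }
  # a genuine straight edge concentrates votes in one bin in proportion to
  # the contour extent; curved boundaries (e.g. circular blobs) spread them
  min_support <- max(10, 0.3 * max(r1 - r0 + 1, c1 - c0 + 1))
  peaks <- peaks[peaks$count >= min_support, , drop = FALSE]
  if (nrow(peaks) < 2) {
    return(NULL)
  }
  p1 <- peaks[1, ]
  best <- NULL
  for (k in 2:nrow(peaks)) {
    p2 <- peaks[k, ]
    if (ang_dist_180(p2$theta, p1$theta) > config$parallel_tol_deg) next
    rho2 <- if (abs(p2$theta - p1$theta) > 90) -p2$rho else p2$rho
    sep <- abs(rho2 - p1$rho)
    if (sep < config$width_range_px[1] || sep > config$width_range_px[2]) next
    best <- p2
    break
  }
  if (is.null(best)) {
    return(NULL)
  }
  list(
    line_from_theta_rho(p1$theta, p1$rho),
    line_from_theta_rho(best$theta, best$rho)
  )
}

#' Midline of the probe from its two edge lines
#'
#' Angles are averaged in normal-angle space (so near-vertical edges do not
#' blow up the slope) and the offset is the mean signed distance, which makes
#' the midline bisect the perpendicular gap between the edges.
#'
#' @param edges list of two [line2d()] objects.
#' @param parallel_tol_deg maximum allowed angle between the edges.
#' @return a [line2d()] midline.
#' @export
midline <- function(edges, parallel_tol_deg = 5) {
  stopifnot(length(edges) == 2)
  a <- line_theta_rho(edges[[1]])
  b <- line_theta_rho(edges[[2]])
  if (ang_dist_180(a["theta"], b["theta"]) > parallel_tol_deg) {
    stop("edges are not near-parallel")
  }
  th2 <- b["theta"]
  rho2 <- b["rho"]
  if (abs(th2 - a["theta"]) > 90) {
    th2 <- th2 - sign(th2 - a["theta"]) * 180
    rho2 <- -rho2
  }
  line_from_theta_rho((a["theta"] + th2) / 2, (a["rho"] + rho2) / 2)
}

#' Run the full detector on one frame
#'
#' preprocess, HSV conversion, threshold + morphology, largest contour,
#' Hough edges, midline.
#'
#' @param frame RGB array.
#' @param config a [detector_config()].
#' @return list with `valid` flag and, when valid, `mask`, `area`,
#'   `edges` (two [line2d()]), `midline`.
#' @export
detect_frame <- function(frame, config = detector_config()) {
  pre <- preprocess_frame(frame, config)
  hsv <- rgb_to_hsv_frame(pre)
  mask <- segment_marker(hsv, config$range, config)
  contour <- select_contour(mask, min_area = config$min_area)
  if (is.null(contour)) {
    return(list(valid = FALSE, mask = mask))
  }
  edges <- probe_edges(mask, contour, config)
  if (is.null(edges)) {
    return(list(valid = FALSE, mask = mask, area = contour$area))
  }
  mid <- tryCatch(
    midline(edges, config$parallel_tol_deg),
    error = function(e) NULL
  )
  if (is.null(mid)) {
    return(list(valid = FALSE, mask = mask, area = contour$area))
  }
  list(
    valid = TRUE, mask = mask, area = contour$area,
    edges = edges, midline = mid
  )
}
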
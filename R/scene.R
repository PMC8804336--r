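#' Configuration for the synthetic probe scene generator
#'
#' Describes a benchtop scanning scene: a cylindrical probe carrying a colored
#' marker band moves over a tissue-colored background along a commanded
#' trajectory.  The renderer draws the probe as the 2-D projection of the
#' cylinder (a rotated rectangle) with a short unmarked ferrule of
#' `tip_offset_mm` between the end of the marker band and the physical tip, so
#' that the tip and the marker end are distinct, testable points.
#'
#' @param image_size integer `c(width, height)` in pixels.
#' @param marker_color `"green"` or `"cyan"`; hue 120 or 180 degrees.
#' @param marker_length_mm length of the tape band along the probe axis
#'   (default 70 mm).
#' @param probe_diameter_mm width of the probe cylinder.
#' @param tip_offset_mm distance from the tip-side end of the marker band to
#'   the physical tip, along the midline.
#' @param mm_per_px ground-truth scale of the scene.
#' @param background_hue_range hue interval (degrees) from which tissue blob
#'   hues are drawn.  When the first bound exceeds the second the interval
#'   wraps through 0; the default `c(300, 30)` spans the purple-red-yellow
#'   arc of biological tissue, which stresses the detector without
#'   containing the green/cyan marker hues.
#' @param trajectory data frame or matrix with columns `x`, `y`, `yaw_deg`:
#'   commanded tip position (pixels) and probe yaw per frame.  Yaw is the
#'   counter-clockwise angle of the probe axis on the displayed image; for yaw
#'   in (0, 180) the tip is the lower (larger-y) end of the probe.
#' @param occlusion_spans list of integer `c(first, last)` frame intervals
#'   (1-based, inclusive) during which the tip-side portion of the marker is
#'   covered.
#' @param occlusion_cover fraction of the marker band (from the tip end)
#'   hidden during occlusion spans.
#' @param illumination_gain scalar or per-frame vector multiplying the
#'   rendered frame (clamped to `[0, 1]`).
#' @param noise_sd standard deviation of additive per-pixel sensor noise.
#' @param seed integer; fixes the rendered output bit-exactly.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(image_size = c(640, 480),
                         marker_color = c("green", "cyan"),
                         marker_length_mm = 70,
                         probe_diameter_mm = 6,
                         tip_offset_mm = 5,
                         mm_per_px = 0.28,
                         background_hue_range = c(300, 30),
                         trajectory,
                         occlusion_spans = NULL,
                         occlusion_cover = 0.8,
                         illumination_gain = 1,
                         noise_sd = 0.01,
                         seed = 1) {
  marker_color <- match.arg(marker_color)
  stopifnot(
    length(image_size) == 2, all(image_size > 0),
    marker_length_mm > 0, probe_diameter_mm > 0, tip_offset_mm >= 0,
    mm_per_px > 0, noise_sd >= 0,
    occlusion_cover >= 0, occlusion_cover <= 1
  )
  trajectory <- as.data.frame(trajectory)
  if (!all(c("x", "y", "yaw_deg") %in% names(trajectory))) {
    names(trajectory)[1:3] <- c("x", "y", "yaw_deg")
  }
  stopifnot(nrow(trajectory) >= 1)
  if (any(trajectory$yaw_deg < 0 | trajectory$yaw_deg >= 360)) {
    stop("yaw must lie in [0, 360)")
  }
  n <- nrow(trajectory)
  gain <- rep_len(illumination_gain, n)
  structure(
    list(
      image_size = as.integer(image_size),
      marker_color = marker_color,
      marker_length_mm = marker_length_mm,
      probe_diameter_mm = probe_diameter_mm,
      tip_offset_mm = tip_offset_mm,
      mm_per_px = mm_per_px,
      background_hue_range = background_hue_range,
      trajectory = trajectory,
      occlusion_spans = occlusion_spans,
      occlusion_cover = occlusion_cover,
      illumination_gain = gain,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "scene_config"
  )
}

#' Straight-line trajectory helper
#'
#' @param n number of frames.
#' @param from,to tip position `c(x, y)` at the first and last frame.
#' @param yaw_deg constant probe yaw in degrees.
#' @return data frame with columns `x`, `y`, `yaw_deg`.
#' @export
linear_trajectory <- function(n, from, to, yaw_deg = 60) {
  s <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
  data.frame(
    x = from[1] + s * (to[1] - from[1]),
    y = from[2] + s * (to[2] - from[2]),
    yaw_deg = rep(yaw_deg, n)
  )
}

marker_hsv <- function(color) {
  switch(color,
    green = c(h = 120, s = 0.85, v = 0.80),
    cyan = c(h = 180, s = 0.85, v = 0.80)
  )
}

# evaluate expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Render the static tissue background of a scene
#'
#' Smooth colored blobs with hues sampled in `background_hue_range`
#' (yellow through purple) over a neutral tissue tone.  The field is built at
#' quarter resolution and upsampled, which keeps it smooth and cheap.  The
#' background depends only on the config and its seed, so it is rendered once
#' per scene and shared by all frames.
#'
#' @param config a [scene_config()].
#' @return numeric array `c(height, width, 3)`, RGB in `[0, 1]`.
#' @export
scene_background <- function(config) {
  w <- config$image_size[1]
  h <- config$image_size[2]
  ws <- max(8L, as.integer(ceiling(w / 4)))
  hs <- max(8L, as.integer(ceiling(h / 4)))
  with_seed(config$seed, {
    k <- 8L
    cx <- runif(k, 0, ws)
    cy <- runif(k, 0, hs)
    sg <- runif(k, 10, 35)
    hr <- config$background_hue_range
    if (hr[1] > hr[2]) hr[1] <- hr[1] - 360 # wrapped interval through 0
    hue <- runif(k, hr[1], hr[2])
    sat <- runif(k, 0.35, 0.75)
    val <- runif(k, 0.35, 0.85)
    xg <- matrix(rep(seq_len(ws), each = hs), hs, ws)
    yg <- matrix(rep(seq_len(hs), times = ws), hs, ws)
    # base tissue tone: muted red-brown
    wsum <- matrix(0.35, hs, ws)
    hacc <- 25 * wsum
    sacc <- 0.45 * wsum
    vacc <- 0.55 * wsum
    for (i in seq_len(k)) {
      g <- exp(-((xg - cx[i])^2 + (yg - cy[i])^2) / (2 * sg[i]^2))
      wsum <- wsum + g
      hacc <- hacc + hue[i] * g
      sacc <- sacc + sat[i] * g
      vacc <- vacc + val[i] * g
    }
    small <- hsv_to_rgb_frame(hacc / wsum, sacc / wsum, vacc / wsum)
    resize_frame(small, width = w, height = h)
  })
}

# Blend an anti-aliased rotated rectangle into `img`.  The rectangle runs from
# p0 to p1 along its axis with the given half-width; coverage is approximated
# from the axial signed distances, giving ~1 px soft edges.
draw_band <- function(img, p0, p1, halfwidth, rgb) {
  h <- dim(img)[1]
  w <- dim(img)[2]
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  if (len < 1e-9) {
    return(img)
  }
  u <- d / len
  n <- c(-u[2], u[1])
  pad <- halfwidth + 2
  x_lo <- max(1, floor(min(p0[1], p1[1]) - pad))
  x_hi <- min(w, ceiling(max(p0[1], p1[1]) + pad))
  y_lo <- max(1, floor(min(p0[2], p1[2]) - pad))
  y_hi <- min(h, ceiling(max(p0[2], p1[2]) + pad))
  if (x_lo > x_hi || y_lo > y_hi) {
    return(img) # band entirely outside the image
  }
  xs <- x_lo:x_hi
  ys <- y_lo:y_hi
  X <- matrix(rep(xs, each = length(ys)), length(ys), length(xs))
  Y <- matrix(rep(ys, times = length(xs)), length(ys), length(xs))
  ax <- (X - p0[1]) * u[1] + (Y - p0[2]) * u[2]
  px <- (X - p0[1]) * n[1] + (Y - p0[2]) * n[2]
  cov_axis <- pmin(pmax(ax + 0.5, 0), 1) * pmin(pmax(len - ax + 0.5, 0), 1)
  cov_perp <- pmin(pmax(halfwidth - abs(px) + 0.5, 0), 1)
  alpha <- cov_axis * cov_perp
  for (ch in 1:3) {
    sub <- img[ys, xs, ch]
    img[ys, xs, ch] <- sub * (1 - alpha) + rgb[ch] * alpha
  }
  img
}

# unit vector along the probe axis pointing from the tip toward the shaft,
# for a yaw angle measured CCW on the displayed image (y down)
yaw_axis <- function(yaw_deg) {
  a <- yaw_deg * pi / 180
  c(cos(a), -sin(a))
}

#' Render one frame of a synthetic scene
#'
#' @param config a [scene_config()].
#' @param index 1-based frame index into the trajectory.
#' @param background optional precomputed [scene_background()]; pass it when
#'   rendering many frames.
#' @return numeric array `c(height, width, 3)`, RGB in `[0, 1]`.
#' @export
render_frame <- function(config, index, background = NULL) {
  stopifnot(index >= 1, index <= nrow(config$trajectory))
  if (is.null(background)) {
    background <- scene_background(config)
  }
  pose <- config$trajectory[index, ]
  img <- background
  px <- 1 / config$mm_per_px
  u <- yaw_axis(pose$yaw_deg)
  tip <- c(pose$x, pose$y)
  m0 <- tip + config$tip_offset_mm * px * u        # tip-side end of the band
  m1 <- m0 + config$marker_length_mm * px * u      # far end of the band
  shaft_end <- m1 + 40 * u                         # bare shaft past the band
  halfw <- config$probe_diameter_mm * px / 2
  body_rgb <- c(0.80, 0.80, 0.78)
  mk <- marker_hsv(config$marker_color)
  marker_rgb <- as.vector(hsv_to_rgb_frame(mk["h"], mk["s"], mk["v"]))
  img <- draw_band(img, tip, shaft_end, halfw, body_rgb)
  img <- draw_band(img, m0, m1, halfw, marker_rgb)
  occluded <- FALSE
  if (!is.null(config$occlusion_spans)) {
    for (sp in config$occlusion_spans) {
      if (index >= sp[1] && index <= sp[2]) occluded <- TRUE
    }
  }
  if (occluded && config$occlusion_cover > 0) {
    cover_rgb <- c(mean(background[, , 1]), mean(background[, , 2]), mean(background[, , 3]))
    cov_len <- config$occlusion_cover * config$marker_length_mm * px +
      config$tip_offset_mm * px
    img <- draw_band(img, tip - 3 * u, tip + cov_len * u, halfw + 3, cover_rgb)
  }
  gain <- config$illumination_gain[index]
  img <- img * gain
  if (config$noise_sd > 0) {
    # luminance (sensor) noise: one realization shared by the three channels
    frame_seed <- (config$seed * 100003 + index) %% .Machine$integer.max
    nz <- with_seed(frame_seed, matrix(
      stats::rnorm(prod(dim(img)[1:2]), 0, config$noise_sd), dim(img)[1]
    ))
    img <- img + as.vector(nz)
  }
  pmin(pmax(img, 0), 1)
}

#' Ground-truth tip table of a scene
#'
#' One row per frame echoing the commanded pose, with `in_view` flagging tips
#' inside the image bounds and `occluded` flagging frames within an occlusion
#' span.
#'
#' @param config a [scene_config()].
#' @return data frame with columns `frame`, `x`, `y`, `yaw_deg`, `in_view`,
#'   `occluded`.
#' @export
scene_truth <- function(config) {
  tr <- config$trajectory
  n <- nrow(tr)
  occ <- rep(FALSE, n)
  if (!is.null(config$occlusion_spans)) {
    for (sp in config$occlusion_spans) {
      occ[seq_len(n) >= sp[1] & seq_len(n) <= sp[2]] <- TRUE
    }
  }
  data.frame(
    frame = seq_len(n),
    x = tr$x,
    y = tr$y,
    yaw_deg = tr$yaw_deg,
    in_view = tr$x >= 1 & tr$x <= config$image_size[1] &
      tr$y >= 1 & tr$y <= config$image_size[2],
    occluded = occ
  )
}

#' Render a whole scene
#'
#' @param config a [scene_config()].
#' @param out_dir if non-`NULL`, frames are written as numbered PNG files with
#'   a `manifest.csv` index and `truth.csv` ground-truth table, and file paths
#'   are returned instead of in-memory frames.
#' @return list with `truth` (data frame) and either `frames` (list of arrays)
#'   or `paths` (character vector of PNG files).
#' @export
render_scene <- function(config, out_dir = NULL) {
  bg <- scene_background(config)
  truth <- scene_truth(config)
  n <- nrow(truth)
  if (is.null(out_dir)) {
    frames <- vector("list", n)
    for (i in seq_len(n)) frames[[i]] <- render_frame(config, i, bg)
    return(list(frames = frames, truth = truth))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, sprintf("frame_%05d.png", seq_len(n)))
  for (i in seq_len(n)) write_frame_png(render_frame(config, i, bg), paths[i])
  utils::write.csv(
    data.frame(frame = seq_len(n), file = basename(paths)),
    file.path(out_dir, "manifest.csv"),
    row.names = FALSE
  )
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  list(paths = paths, truth = truth)
}
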
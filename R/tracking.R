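#' Locate the probe tip along the midline
#'
#' The mask is sampled at 1 px steps along the midline (with a one-pixel
#' perpendicular tolerance).  The extreme transitions of the resulting 1-D
#' profile give the two candidate ends of the marker band; the tip end is
#' chosen by the configured direction rule, which encodes the benchtop
#' assumption that probe yaw stays within 0-180 degrees.  The physical tip
#' is the chosen end displaced `tip_offset_px` further along the midline,
#' away from the marker.
#'
#' @param mask logical mask from [segment_marker()].
#' @param mid a [line2d()] midline.
#' @param config a [detector_config()] (`tip_rule`, `tip_offset_px`,
#'   `band_px_range`).
#' @return list with `valid` and, when valid, `x`, `y`, `yaw_deg`, `band_px`.
#' @export
locate_tip <- function(mask, mid, config = detector_config()) {
  h <- nrow(mask)
  w <- ncol(mask)
  tr <- line_theta_rho(mid)
  if (any(!is.finite(tr))) {
    return(list(valid = FALSE))
  }
  th <- tr["theta"] * pi / 180
  n <- c(cos(th), sin(th)) # unit normal
  d <- c(-sin(th), cos(th)) # unit direction along the line
  p0 <- tr["rho"] * n
  # parameter range of the line inside the image
  tmax <- sqrt(h^2 + w^2)
  ts <- seq(-tmax, tmax, by = 1)
  px <- p0[1] + ts * d[1]
  py <- p0[2] + ts * d[2]
  inb <- px >= 1 & px <= w & py >= 1 & py <= h
  if (!any(inb)) {
    return(list(valid = FALSE))
  }
  ts <- ts[inb]
  px <- px[inb]
  py <- py[inb]
  sample_at <- function(ox, oy) {
    xi <- pmin(pmax(round(px + ox), 1), w)
    yi <- pmin(pmax(round(py + oy), 1), h)
    mask[cbind(yi, xi)]
  }
  prof <- sample_at(0, 0) | sample_at(n[1], n[2]) | sample_at(-n[1], -n[2])
  if (!any(prof)) {
    return(list(valid = FALSE))
  }
  # close gaps of up to 2 samples, then take the longest run
  r <- rle(prof)
  gap <- !r$values & r$lengths <= 2
  gap[1] <- FALSE
  gap[length(gap)] <- FALSE
  r$values[gap] <- TRUE
  prof2 <- inverse.rle(r)
  r2 <- rle(prof2)
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths + 1
  runs <- which(r2$values)
  if (length(runs) == 0) {
    return(list(valid = FALSE))
  }
  main <- runs[which.max(r2$lengths[runs])]
  i0 <- starts[main]
  i1 <- ends[main]
  # the 1 -> 0 transitions sit half a sample beyond the run ends
  t_a <- ts[i0] - if (i0 > 1) 0.5 else 0
  t_b <- ts[i1] + if (i1 < length(ts)) 0.5 else 0
  band_px <- t_b - t_a
  if (!is.null(config$band_px_range)) {
    if (band_px < config$band_px_range[1] || band_px > config$band_px_range[2]) {
      return(list(valid = FALSE, band_px = band_px))
    }
  }
  pa <- p0 + t_a * d
  pb <- p0 + t_b * d
  larger_y_first <- pa[2] > pb[2] ||
    (abs(pa[2] - pb[2]) < 1e-9 && pa[1] < pb[1]) # tie: bottom-left convention
  chosen <- if (config$tip_rule == "max_y") {
    if (larger_y_first) pa else pb
  } else {
    if (larger_y_first) pb else pa
  }
  other <- if (all(chosen == pa)) pb else pa
  u <- (chosen - other) / sqrt(sum((chosen - other)^2))
  tip <- chosen + config$tip_offset_px * u
  yaw <- (atan2(-u[2], u[1]) * 180 / pi) %% 180
  list(
    valid = TRUE,
    x = unname(tip[1]), y = unname(tip[2]),
    yaw_deg = unname(yaw), band_px = unname(band_px)
  )
}

#' Kalman tracker configuration
#'
#' Constant-velocity model over state `(x, y, vx, vy)` in px and px/frame.
#' Defaults put the steady-state position gain near one half at the typical
#' detection jitter of about 2 px.
#'
#' @param Q 4 x 4 process noise covariance.
#' @param R_m 2 x 2 measurement noise covariance.
#' @param P0 4 x 4 initial covariance (used before the two-point velocity
#'   initialization refines it).
#' @param max_coast number of consecutive missed detections tolerated before
#'   the track is dropped (15 frames, half a second at 30 fps).
#' @return object of class `track_config`.
#' @export
track_config <- function(Q = diag(c(0.01, 0.01, 0.1, 0.1)),
                         R_m = diag(c(4, 4)),
                         P0 = diag(100, 4),
                         max_coast = 15) {
  structure(
    list(Q = Q, R_m = R_m, P0 = P0, max_coast = as.integer(max_coast)),
    class = "track_config"
  )
}

#' Create a Kalman track state
#'
#' @param x,y initial tip position (px).
#' @param vx,vy initial velocity (px/frame).
#' @param config a [track_config()].
#' @param P initial covariance; defaults to `config$P0`.
#' @return object of class `track_state` with fields `state`, `P`, `Q`,
#'   `R_m`.
#' @export
kf_create <- function(x, y, vx = 0, vy = 0, config = track_config(), P = NULL) {
  structure(
    list(
      state = c(x = x, y = y, vx = vx, vy = vy),
      P = if (is.null(P)) config$P0 else P,
      Q = config$Q,
      R_m = config$R_m
    ),
    class = "track_state"
  )
}

kf_F <- rbind(
  c(1, 0, 1, 0),
  c(0, 1, 0, 1),
  c(0, 0, 1, 0),
  c(0, 0, 0, 1)
)
kf_H <- rbind(
  c(1, 0, 0, 0),
  c(0, 1, 0, 0)
)

#' Kalman predict step
#'
#' Constant-velocity transition: position advances by the velocity, the
#' covariance is propagated and inflated by the process noise.
#'
#' @param track a `track_state`.
#' @return the predicted `track_state`.
#' @export
kf_predict <- function(track) {
  track$state <- as.vector(kf_F %*% track$state)
  names(track$state) <- c("x", "y", "vx", "vy")
  P <- kf_F %*% track$P %*% t(kf_F) + track$Q
  track$P <- (P + t(P)) / 2
  track
}

#' Kalman update (correction) step
#'
#' Standard gain `K = P H' (H P H' + R)^-1`; the covariance is updated in
#' Joseph form, which keeps it symmetric positive-definite.
#'
#' @param track a predicted `track_state`.
#' @param z measurement `c(x, y)` in px.
#' @return the corrected `track_state`.
#' @export
kf_update <- function(track, z) {
  P <- track$P
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("numerical failure: track covariance is not positive definite")
  }
  S <- kf_H %*% P %*% t(kf_H) + track$R_m
  K <- P %*% t(kf_H) %*% solve(S)
  innov <- z[1:2] - as.vector(kf_H %*% track$state)
  track$state <- as.vector(track$state + K %*% innov)
  names(track$state) <- c("x", "y", "vx", "vy")
  IKH <- diag(4) - K %*% kf_H
  P <- IKH %*% P %*% t(IKH) + K %*% track$R_m %*% t(K)
  track$P <- (P + t(P)) / 2
  track
}

#' Smooth a sequence of per-frame tip detections
#'
#' Per frame: predict; when a detection is available, correct and emit the
#' posterior with `source = "detected"`; otherwise emit the prediction with
#' `source = "predicted"`.  The track is initialized from the first
#' detection, with the velocity set from the first two detections; after
#' `max_coast` consecutive misses the track is dropped until re-detection.
#'
#' @param detections data frame with columns `frame`, `valid`, `x`, `y` and
#'   optionally `yaw_deg`, ordered by frame.
#' @param config a [track_config()].
#' @return data frame `frame`, `x`, `y`, `source`, `yaw_deg` (one row per
#'   emitted frame; frames before initialization or after a drop are absent).
#' @export
track_sequence <- function(detections, config = track_config()) {
  det <- as.data.frame(detections)
  stopifnot(all(c("frame", "valid", "x", "y") %in% names(det)))
  if (is.null(det$yaw_deg)) det$yaw_deg <- NA_real_
  out <- vector("list", nrow(det))
  track <- NULL
  pending <- NULL # first detection, waiting for a second to set velocity
  coast <- 0L
  last_yaw <- NA_real_
  for (i in seq_len(nrow(det))) {
    row <- det[i, ]
    has_z <- isTRUE(row$valid)
    if (has_z && !is.na(row$yaw_deg)) last_yaw <- row$yaw_deg
    if (is.null(track)) {
      if (has_z) {
        if (!is.null(pending)) {
          g <- row$frame - pending$frame
          if (g <= config$max_coast && g >= 1) {
            v <- c(row$x - pending$x, row$y - pending$y) / g
            r <- config$R_m[1, 1]
            P <- diag(c(r, r, 2 * r / g^2 + 1, 2 * r / g^2 + 1))
            track <- kf_create(row$x, row$y, v[1], v[2], config, P = P)
            coast <- 0L
            pending <- NULL
            out[[i]] <- data.frame(
              frame = row$frame, x = row$x, y = row$y,
              source = "detected", yaw_deg = last_yaw
            )
            next
          }
        }
        pending <- row
        out[[i]] <- data.frame(
          frame = row$frame, x = row$x, y = row$y,
          source = "detected", yaw_deg = last_yaw
        )
      }
      next
    }
    track <- kf_predict(track)
    if (has_z) {
      track <- kf_update(track, c(row$x, row$y))
      coast <- 0L
      src <- "detected"
    } else {
      coast <- coast + 1L
      if (coast > config$max_coast) {
        track <- NULL
        pending <- NULL
        next
      }
      src <- "predicted"
    }
    out[[i]] <- data.frame(
      frame = row$frame, x = track$state[["x"]], y = track$state[["y"]],
      source = src, yaw_deg = last_yaw
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(
      frame = integer(0), x = numeric(0), y = numeric(0),
      source = character(0), yaw_deg = numeric(0)
    )
  }
  rownames(res) <- NULL
  res
}

#' Detect and track the probe tip through a rendered scene
#'
#' Streams through the frames of a synthetic scene (rendering, detection and
#' tip localization frame by frame, without holding the video in memory) and
#' Kalman-smooths the detections.
#'
#' @param scene a [scene_config()].
#' @param detector a [detector_config()]; its `tip_offset_px` should match
#'   the scene geometry (`tip_offset_mm / mm_per_px`) for an unbiased tip.
#' @param tracker a [track_config()].
#' @return list with `detections` (per-frame data frame), `track` (smoothed
#'   output of [track_sequence()]) and `truth` (from [scene_truth()]).
#' @export
track_scene <- function(scene,
                        detector = NULL,
                        tracker = track_config()) {
  if (is.null(detector)) {
    detector <- detector_config(
      marker_color = scene$marker_color,
      tip_offset_px = scene$tip_offset_mm / scene$mm_per_px
    )
  }
  bg <- scene_background(scene)
  n <- nrow(scene$trajectory)
  det <- data.frame(
    frame = seq_len(n), valid = FALSE,
    x = NA_real_, y = NA_real_, yaw_deg = NA_real_, band_px = NA_real_
  )
  for (i in seq_len(n)) {
    frame <- render_frame(scene, i, bg)
    d <- detect_frame(frame, detector)
    if (!d$valid) next
    tip <- locate_tip(d$mask, d$midline, detector)
    if (!tip$valid) next
    det$valid[i] <- TRUE
    det$x[i] <- tip$x
    det$y[i] <- tip$y
    det$yaw_deg[i] <- tip$yaw_deg
    det$band_px[i] <- tip$band_px
  }
  list(
    detections = det,
    track = track_sequence(det, tracker),
    truth = scene_truth(scene)
  )
}

#' Write / read a track CSV
#'
#' Columns `frame`, `x`, `y`, `source`, `yaw_deg`; the format consumed by
#' [evaluate_tracking()] and the session tools.
#'
#' @param track data frame from [track_sequence()].
#' @param path CSV path.
#' @return invisibly `path` (write) / the data frame (read).
#' @export
write_track_csv <- function(track, path) {
  utils::write.csv(track, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  utils::read.csv(path)
}
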
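#' Probability colormap for the overlay
#'
#' Linear interpolation from pure green (probability 0, normal) to pink
#' (probability 1, tumor).
#'
#' @param p tumor probability (vectorized), each value in `[0, 1]`.
#' @return matrix with columns `r`, `g`, `b` in 0-255 (one row per
#'   probability).
#' @export
probability_color <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p))) {
    stop("probability must lie in [0, 1]")
  }
  green <- c(0, 255, 0)
  pink <- c(255, 105, 180)
  out <- cbind(
    r = green[1] + p * (pink[1] - green[1]),
    g = green[2] + p * (pink[2] - green[2]),
    b = green[3] + p * (pink[3] - green[3])
  )
  out
}

#' Evaluate tracking accuracy against labeled ground truth
#'
#' Compares an estimated tip track with one or two manually labeled tracks
#' on the frames both share.  Per axis and per labeler: root mean squared
#' error, maximum and minimum absolute error, in pixels and (via
#' `mm_per_px`) in millimetres.  With two label sets each is evaluated
#' separately and their mean is the headline figure.
#'
#' @param estimated data frame with columns `frame`, `x`, `y`.
#' @param labels one data frame `frame, x, y`, or a list of 1-2 of them.
#' @param mm_per_px pixel-to-millimetre scale (see [mm_per_pixel()]).
#' @return object of class `tracking_error_report`: `per_labeler` (data
#'   frame: labeler, axis, rmse_px, max_px, min_px, rmse_mm, max_mm,
#'   min_mm, n_frames) and `mean` (averaged over labelers).
#' @export
evaluate_tracking <- function(estimated, labels, mm_per_px = 1) {
  if (is.data.frame(labels)) labels <- list(labels)
  stopifnot(length(labels) >= 1, length(labels) <= 2, mm_per_px > 0)
  rows <- list()
  for (li in seq_along(labels)) {
    lab <- labels[[li]]
    common <- intersect(estimated$frame, lab$frame)
    if (length(common) == 0) {
      stop("no overlapping frames between estimate and labels")
    }
    e <- estimated[match(common, estimated$frame), ]
    l <- lab[match(common, lab$frame), ]
    for (axis in c("x", "y")) {
      d <- e[[axis]] - l[[axis]]
      rows[[length(rows) + 1]] <- data.frame(
        labeler = li, axis = axis,
        rmse_px = sqrt(mean(d^2)),
        max_px = max(abs(d)),
        min_px = min(abs(d)),
        n_frames = length(common)
      )
    }
  }
  per <- do.call(rbind, rows)
  per$rmse_mm <- per$rmse_px * mm_per_px
  per$max_mm <- per$max_px * mm_per_px
  per$min_mm <- per$min_px * mm_per_px
  mean_df <- do.call(rbind, lapply(c("x", "y"), function(axis) {
    sub <- per[per$axis == axis, ]
    data.frame(
      axis = axis,
      rmse_px = mean(sub$rmse_px), max_px = mean(sub$max_px),
      min_px = mean(sub$min_px),
      rmse_mm = mean(sub$rmse_mm), max_mm = mean(sub$max_mm),
      min_mm = mean(sub$min_mm),
      n_frames = sub$n_frames[1]
    )
  }))
  structure(
    list(per_labeler = per, mean = mean_df, mm_per_px = mm_per_px),
    class = "tracking_error_report"
  )
}

#' @export
print.tracking_error_report <- function(x, ...) {
  cat("<tracking_error_report>\n")
  m <- x$mean
  for (i in seq_len(nrow(m))) {
    cat(sprintf(
      "  %s: RMSE %.2f px (%.2f mm), max %.2f px, min %.2f px over %d frames\n",
      m$axis[i], m$rmse_px[i], m$rmse_mm[i], m$max_px[i], m$min_px[i],
      m$n_frames[i]
    ))
  }
  invisible(x)
}

# alpha-blend a filled disc into a frame
draw_disc <- function(frame, x, y, radius, rgb255, alpha = 0.6) {
  h <- dim(frame)[1]
  w <- dim(frame)[2]
  xs <- max(1L, floor(x - radius - 1)):min(w, ceiling(x + radius + 1))
  ys <- max(1L, floor(y - radius - 1)):min(h, ceiling(y + radius + 1))
  if (length(xs) == 0 || length(ys) == 0) {
    return(frame)
  }
  X <- matrix(rep(xs, each = length(ys)), length(ys), length(xs))
  Y <- matrix(rep(ys, times = length(xs)), length(ys), length(xs))
  d <- sqrt((X - x)^2 + (Y - y)^2)
  a <- alpha * pmin(pmax(radius - d + 0.5, 0), 1)
  for (ch in 1:3) {
    sub <- frame[ys, xs, ch]
    frame[ys, xs, ch] <- sub * (1 - a) + (rgb255[ch] / 255) * a
  }
  frame
}

#' Annotate a frame with the biopsy-site registry
#'
#' Draws every site as a semi-transparent disc of its footprint radius in
#' its probability color.  A site's drawn position is fixed, so in a
#' static-camera session it is identical in every frame.
#'
#' @param frame RGB array.
#' @param sites data frame with columns `x`, `y`, `radius_px`,
#'   `probability`.
#' @return annotated frame.
#' @export
annotate_frame <- function(frame, sites) {
  if (is.null(sites) || nrow(sites) == 0) {
    return(frame)
  }
  for (i in seq_len(nrow(sites))) {
    col <- probability_color(sites$probability[i])[1, ]
    frame <- draw_disc(
      frame, sites$x[i], sites$y[i], sites$radius_px[i], col
    )
  }
  frame
}

#' Run a scanning session end to end
#'
#' Streams the scene through detection and Kalman tracking; at every trigger
#' frame (the offline stand-in for the GUI's "get spectrum" button) the
#' current smoothed tip becomes a biopsy site whose footprint is the probe
#' ferrule (0.125 in = 3.175 mm diameter, converted with `mm_per_px`).  The
#' trigger's replicate spectra are processed and scored by the supplied
#' classifier; sites are re-projected onto every subsequent frame of the
#' annotated output.  Triggers with no live track are rejected and logged.
#'
#' @param scene a [scene_config()].
#' @param triggers integer frame indices at which spectra are acquired.
#' @param spectra_sim optional [spectra_sim_config()]; trigger `i` consumes
#'   site `i` of the simulated acquisition.  `NULL` skips spectral scoring.
#' @param classifier optional [train_classifier()] result used to score each
#'   site's mean spectrum.
#' @param detector,tracker detector and tracker configurations (defaults
#'   derived from the scene as in [track_scene()]).
#' @param mm_per_px pixel scale for the footprint (defaults to the scene's).
#' @param out_dir optional archive directory: annotated PNG frames,
#'   `sites.csv`, `track.csv`, `config.json` and a text log are written.
#' @param annotate when `TRUE` (default only if `out_dir` is given),
#'   annotated frames are rendered.
#' @return list with `sites` (registry data frame), `track`, `detections`,
#'   `truth`, `log` (character), and `archive` (paths, when written).
#' @export
run_session <- function(scene, triggers, spectra_sim = NULL, classifier = NULL,
                        detector = NULL, tracker = track_config(),
                        mm_per_px = NULL, out_dir = NULL,
                        annotate = !is.null(out_dir)) {
  if (is.null(mm_per_px)) mm_per_px <- scene$mm_per_px
  res <- track_scene(scene, detector, tracker)
  track <- res$track
  log <- character(0)
  ferrule_mm <- 3.175
  radius_px <- ferrule_mm / 2 / mm_per_px
  spectra <- NULL
  if (!is.null(spectra_sim)) {
    sim <- simulate_spectra(spectra_sim)
    spectra <- process_spectra(sim)
  }
  sites <- list()
  for (i in seq_along(triggers)) {
    fr <- triggers[i]
    row <- track[track$frame == fr, ]
    if (nrow(row) == 0) {
      log <- c(log, sprintf(
        "trigger at frame %d rejected: no valid track", fr
      ))
      next
    }
    prob <- NA_real_
    if (!is.null(classifier) && !is.null(spectra) &&
          i <= nrow(spectra$features)) {
      prob <- predict_site(classifier, spectra$features[i, ])
    }
    sites[[length(sites) + 1]] <- data.frame(
      site_id = sprintf("site_%03d", length(sites) + 1),
      frame = fr,
      x = row$x, y = row$y,
      source = row$source,
      radius_px = radius_px,
      probability = prob
    )
    log <- c(log, sprintf(
      "trigger at frame %d accepted (source=%s)", fr, row$source
    ))
  }
  sites <- if (length(sites) > 0) {
    do.call(rbind, sites)
  } else {
    data.frame(
      site_id = character(0), frame = integer(0), x = numeric(0),
      y = numeric(0), source = character(0), radius_px = numeric(0),
      probability = numeric(0)
    )
  }
  archive <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(sites, file.path(out_dir, "sites.csv"), row.names = FALSE)
    write_track_csv(track, file.path(out_dir, "track.csv"))
    jsonlite::write_json(
      list(
        seed = scene$seed, mm_per_px = mm_per_px,
        ferrule_mm = ferrule_mm, triggers = triggers
      ),
      file.path(out_dir, "config.json"),
      auto_unbox = TRUE
    )
    writeLines(log, file.path(out_dir, "session.log"))
    if (annotate) {
      bg <- scene_background(scene)
      n <- nrow(scene$trajectory)
      paths <- file.path(out_dir, sprintf("annotated_%05d.png", seq_len(n)))
      for (f in seq_len(n)) {
        frame <- render_frame(scene, f, bg)
        vis <- sites[sites$frame <= f & !is.na(sites$probability), ]
        if (nrow(vis) == 0) vis <- sites[sites$frame <= f, ]
        vis$probability[is.na(vis$probability)] <- 0
        frame <- annotate_frame(frame, vis)
        write_frame_png(frame, paths[f])
      }
      archive <- list(dir = out_dir, frames = paths)
    } else {
      archive <- list(dir = out_dir)
    }
  }
  list(
    sites = sites, track = track, detections = res$detections,
    truth = res$truth, log = log, archive = archive
  )
}
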
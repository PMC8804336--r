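# Shared fixtures built in code.

# A small scene with the default geometry; n frames of straight motion.
small_scene <- function(n = 5, from = c(150, 300), to = c(200, 330),
                        yaw = 60, seed = 3, ...) {
  scene_config(
    trajectory = linear_trajectory(n, from, to, yaw_deg = yaw),
    seed = seed, ...
  )
}

# Detector matched to a scene's geometry.
scene_detector <- function(scene, ...) {
  detector_config(
    marker_color = scene$marker_color,
    tip_offset_px = scene$tip_offset_mm / scene$mm_per_px,
    ...
  )
}

# Logical mask of the interior of the rendered marker band (1 px inside the
# anti-aliased boundary), from the commanded geometry: the renderer's own
# band-pixel oracle.
band_interior_mask <- function(scene, index, shrink = 1.5) {
  pose <- scene$trajectory[index, ]
  px <- 1 / scene$mm_per_px
  a <- pose$yaw_deg * pi / 180
  u <- c(cos(a), -sin(a))
  nn <- c(-u[2], u[1])
  tip <- c(pose$x, pose$y)
  m0 <- tip + scene$tip_offset_mm * px * u
  len <- scene$marker_length_mm * px
  halfw <- scene$probe_diameter_mm * px / 2
  w <- scene$image_size[1]
  h <- scene$image_size[2]
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), times = w), h, w)
  ax <- (X - m0[1]) * u[1] + (Y - m0[2]) * u[2]
  pp <- (X - m0[1]) * nn[1] + (Y - m0[2]) * nn[2]
  ax >= shrink & ax <= len - shrink & abs(pp) <= halfw - shrink
}

# Noise-free synthetic checkerboard views from a known camera; the forward
# projection is the oracle for the calibration solver.
synthetic_views <- function(K, n_views = 5, noise_sd = 0, seed = 1) {
  rot <- function(rx, ry, rz) {
    Rx <- rbind(c(1, 0, 0), c(0, cos(rx), -sin(rx)), c(0, sin(rx), cos(rx)))
    Ry <- rbind(c(cos(ry), 0, sin(ry)), c(0, 1, 0), c(-sin(ry), 0, cos(ry)))
    Rz <- rbind(c(cos(rz), -sin(rz), 0), c(sin(rz), cos(rz), 0), c(0, 0, 1))
    Rz %*% Ry %*% Rx
  }
  angles <- list(
    c(0.2, 0.1, 0.05), c(-0.25, 0.2, -0.1), c(0.1, -0.3, 0.2),
    c(0.3, 0.25, -0.15), c(-0.15, -0.2, 0.1), c(0.05, 0.35, 0.25)
  )
  ts <- list(
    c(-80, -60, 400), c(-90, -50, 450), c(-70, -65, 380),
    c(-85, -55, 420), c(-75, -60, 440), c(-60, -70, 410)
  )
  board <- as.matrix(expand.grid(X = seq(0, 180, by = 30), Y = seq(0, 120, by = 30)))
  set.seed(seed)
  lapply(seq_len(n_views), function(i) {
    R <- do.call(rot, as.list(angles[[i]]))
    P <- K %*% cbind(R[, 1], R[, 2], ts[[i]])
    uvw <- cbind(board, 1) %*% t(P)
    img <- uvw[, 1:2] / uvw[, 3]
    if (noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), 0, noise_sd), ncol = 2)
    }
    list(board = board, image = img)
  })
}

# Two-class spectra dataset with controllable separation, already processed.
make_dataset <- function(n_per_class = 20, separation = 1, noise_sd = 0.03,
                         outlier_fraction = 0, seed = 1) {
  cfg <- spectra_sim_config(
    n_sites_per_class = n_per_class,
    class_shapes = default_class_shapes(separation),
    noise_sd = noise_sd,
    outlier_fraction = outlier_fraction,
    seed = seed
  )
  list(config = cfg, sim = simulate_spectra(cfg))
}
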
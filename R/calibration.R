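#' Estimate the homography mapping board points to image points
#'
#' Normalized direct linear transform: both point sets are translated and
#' scaled to mean distance sqrt(2) from the origin, the 2n x 9 design matrix
#' is solved by SVD, and the result is denormalized and scaled so the
#' bottom-right entry is 1.
#'
#' @param board n x 2 matrix of planar board coordinates (mm).
#' @param image n x 2 matrix of the corresponding image points (px).
#' @return 3 x 3 homography with `H[3, 3] == 1`.
#' @export
estimate_homography <- function(board, image) {
  board <- as.matrix(board)
  image <- as.matrix(image)
  n <- nrow(board)
  if (n < 4 || nrow(image) != n) {
    stop("at least 4 point correspondences are required")
  }
  if (collinear_points(board) || collinear_points(image)) {
    stop("singular configuration: correspondences are collinear")
  }
  Tb <- normalizing_transform(board)
  Ti <- normalizing_transform(image)
  bh <- apply_h(Tb, board)
  ih <- apply_h(Ti, image)
  A <- matrix(0, 2 * n, 9)
  for (k in seq_len(n)) {
    X <- c(bh[k, 1], bh[k, 2], 1)
    u <- ih[k, 1]
    v <- ih[k, 2]
    A[2 * k - 1, ] <- c(-X, 0, 0, 0, u * X)
    A[2 * k, ] <- c(0, 0, 0, -X, v * X)
  }
  h <- svd(A, nu = 0)$v[, 9]
  H <- solve(Ti) %*% matrix(h, 3, 3, byrow = TRUE) %*% Tb
  H / H[3, 3]
}

collinear_points <- function(p) {
  s <- svd(scale(p, scale = FALSE))$d
  s[2] < 1e-8 * max(s[1], 1)
}

normalizing_transform <- function(p) {
  ctr <- colMeans(p)
  d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
  s <- sqrt(2) / max(mean(d), 1e-12)
  matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1), 3, 3, byrow = TRUE)
}

apply_h <- function(H, p) {
  ph <- cbind(p, 1) %*% t(H)
  ph[, 1:2] / ph[, 3]
}

# Zhang's closed-form constraint vector for the image of the absolute conic
zhang_v <- function(H, i, j) {
  c(
    H[1, i] * H[1, j],
    H[1, i] * H[2, j] + H[2, i] * H[1, j],
    H[2, i] * H[2, j],
    H[3, i] * H[1, j] + H[1, i] * H[3, j],
    H[3, i] * H[2, j] + H[2, i] * H[3, j],
    H[3, i] * H[3, j]
  )
}

#' Estimate camera intrinsics from planar views
#'
#' Closed-form planar (checkerboard) calibration: each view contributes two
#' linear constraints on the image of the absolute conic; the 3 x 3 intrinsic
#' matrix K is recovered from the null vector, and each view's rotation and
#' translation follow from its homography.  Rotations are re-orthonormalized
#' by SVD.  Lens distortion is not estimated.
#'
#' @param views list of views; each view is a list with elements `board`
#'   (n x 2 mm) and `image` (n x 2 px), or a precomputed 3 x 3 homography.
#' @return a `camera_model`: list with `K` (3 x 3 upper-triangular),
#'   `views` (per view `R`, `t`), and `mm_per_px` (`NA` until set via
#'   [mm_per_pixel()]).
#' @export
estimate_intrinsics <- function(views) {
  if (length(views) < 3) {
    stop("at least 3 views with distinct orientations are required")
  }
  Hs <- lapply(views, function(v) {
    if (is.matrix(v) && all(dim(v) == c(3, 3))) v
    else estimate_homography(v$board, v$image)
  })
  V <- do.call(rbind, lapply(Hs, function(H) {
    rbind(zhang_v(H, 1, 2), zhang_v(H, 1, 1) - zhang_v(H, 2, 2))
  }))
  sv <- svd(V, nu = 0)
  if (sv$d[5] < 1e-10 * sv$d[1]) {
    stop("rank deficiency: views do not constrain the intrinsics ",
         "(identical orientations?)")
  }
  b <- sv$v[, 6]
  B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]; B33 <- b[6]
  den <- B11 * B22 - B12^2
  v0 <- (B12 * B13 - B11 * B23) / den
  lam <- B33 - (B13^2 + v0 * (B12 * B13 - B11 * B23)) / B11
  if (lam / B11 < 0) { # b is defined up to sign
    b <- -b
    B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]; B33 <- b[6]
    den <- B11 * B22 - B12^2
    v0 <- (B12 * B13 - B11 * B23) / den
    lam <- B33 - (B13^2 + v0 * (B12 * B13 - B11 * B23)) / B11
  }
  fx <- sqrt(lam / B11)
  fy <- sqrt(lam * B11 / den)
  skew <- -B12 * fx^2 * fy / lam
  u0 <- skew * v0 / fy - B13 * fx^2 / lam
  K <- matrix(c(fx, skew, u0, 0, fy, v0, 0, 0, 1), 3, 3, byrow = TRUE)
  Kinv <- solve(K)
  view_poses <- lapply(Hs, function(H) {
    l <- 1 / sqrt(sum((Kinv %*% H[, 1])^2))
    r1 <- l * Kinv %*% H[, 1]
    r2 <- l * Kinv %*% H[, 2]
    t <- l * Kinv %*% H[, 3]
    if (t[3] < 0) { # board must lie in front of the camera
      r1 <- -r1; r2 <- -r2; t <- -t
    }
    r3 <- c(
      r1[2] * r2[3] - r1[3] * r2[2],
      r1[3] * r2[1] - r1[1] * r2[3],
      r1[1] * r2[2] - r1[2] * r2[1]
    )
    R <- cbind(r1, r2, r3)
    s <- svd(R)
    R <- s$u %*% t(s$v)
    if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
    list(R = R, t = as.vector(t))
  })
  structure(
    list(K = K, views = view_poses, mm_per_px = NA_real_),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(
    "<camera_model: fx=%.2f fy=%.2f cx=%.2f cy=%.2f skew=%.4f, %d views, mm/px=%s>\n",
    x$K[1, 1], x$K[2, 2], x$K[1, 3], x$K[2, 3], x$K[1, 2],
    length(x$views),
    if (is.na(x$mm_per_px)) "unset" else sprintf("%.4f", x$mm_per_px)
  ))
  invisible(x)
}

#' Metric size of one pixel at a working distance
#'
#' Fronto-parallel pinhole convention: a pixel at working distance `d` (cm)
#' spans `10 * d / f` mm on the object plane, with `f` the mean of the two
#' focal lengths in pixels.  This is the scale used to convert tracking
#' errors from pixels to millimetres.
#'
#' @param model a `camera_model`, or a single focal length in px.
#' @param working_distance_cm camera-to-plane distance in cm (default 30).
#' @return scalar mm per pixel.
#' @export
mm_per_pixel <- function(model, working_distance_cm = 30) {
  stopifnot(working_distance_cm > 0)
  f <- if (inherits(model, "camera_model")) {
    (model$K[1, 1] + model$K[2, 2]) / 2
  } else {
    as.numeric(model)
  }
  10 * working_distance_cm / f
}

#' Write a camera model to JSON
#' @param model a `camera_model`.
#' @param path output JSON path.
#' @param working_distance_cm stored alongside (default 30).
#' @return invisibly, `path`.
#' @export
write_camera_json <- function(model, path, working_distance_cm = 30) {
  jsonlite::write_json(
    list(
      K = as.vector(t(model$K)),
      working_distance_cm = working_distance_cm,
      mm_per_px = if (is.na(model$mm_per_px)) {
        mm_per_pixel(model, working_distance_cm)
      } else {
        model$mm_per_px
      }
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a camera model from JSON
#' @param path JSON written by [write_camera_json()] (9 row-major K entries,
#'   working distance and mm/px scale).
#' @return a `camera_model` with `mm_per_px` set.
#' @export
read_camera_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      K = matrix(j$K, 3, 3, byrow = TRUE),
      views = list(),
      mm_per_px = j$mm_per_px,
      working_distance_cm = j$working_distance_cm
    ),
    class = "camera_model"
  )
}
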
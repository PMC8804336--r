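# Frame conventions used throughout the package:
#  * a frame is a numeric array dim c(height, width, 3), RGB in [0, 1];
#  * x is the column index, y the row index, y grows downward;
#  * angles ("yaw") are measured counter-clockwise on the displayed image,
#    in degrees, and probe orientation is taken modulo 180.

#' Gaussian kernel weights
#' @noRd
gaussian_weights <- function(size, sigma) {
  h <- (size - 1) / 2
  w <- exp(-((-h:h)^2) / (2 * sigma^2))
  w / sum(w)
}

# Separable 1-D convolution along matrix columns (i.e. across x), replicate
# boundary.  Shift-and-add keeps this fast enough for video-rate use.
#' @noRd
conv_cols <- function(M, w) {
  r <- length(w)
  h <- (r - 1) / 2
  n <- ncol(M)
  out <- matrix(0, nrow(M), n)
  s <- seq_len(n)
  for (j in seq_len(r)) {
    idx <- pmin(pmax(s + (j - 1 - h), 1L), n)
    out <- out + w[j] * M[, idx, drop = FALSE]
  }
  out
}

#' @noRd
conv_rows <- function(M, w) {
  r <- length(w)
  h <- (r - 1) / 2
  n <- nrow(M)
  out <- matrix(0, n, ncol(M))
  s <- seq_len(n)
  for (j in seq_len(r)) {
    idx <- pmin(pmax(s + (j - 1 - h), 1L), n)
    out <- out + w[j] * M[idx, , drop = FALSE]
  }
  out
}

#' Separable Gaussian blur of a frame or matrix
#'
#' @param frame numeric array `c(h, w, 3)` or matrix.
#' @param size odd kernel size in pixels.
#' @param sigma Gaussian standard deviation in pixels.
#' @return blurred input, same shape.  Constant inputs are returned unchanged
#'   (the kernel is normalized and boundaries are replicated).
#' @export
blur_frame <- function(frame, size = 11, sigma = 2) {
  stopifnot(size %% 2 == 1, sigma > 0)
  w <- gaussian_weights(size, sigma)
  if (is.matrix(frame)) {
    return(conv_rows(conv_cols(frame, w), w))
  }
  stopifnot(length(dim(frame)) == 3)
  out <- frame
  for (ch in seq_len(dim(frame)[3])) {
    out[, , ch] <- conv_rows(conv_cols(frame[, , ch], w), w)
  }
  out
}

#' Resize a frame with bilinear interpolation
#'
#' @param frame numeric array `c(h, w, 3)`.
#' @param width,height target size in pixels.
#' @return resized frame; the input is returned as-is when already at the
#'   target size.
#' @export
resize_frame <- function(frame, width = 640, height = 480) {
  d <- dim(frame)
  stopifnot(length(d) == 3, d[3] == 3)
  if (d[1] == height && d[2] == width) {
    return(frame)
  }
  img <- EBImage::Image(aperm(frame, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(img, w = width, h = height)
  aperm(EBImage::imageData(out), c(2, 1, 3))
}

#' Convert an RGB frame to HSV
#'
#' Standard hexcone conversion.  Hue is returned in degrees `[0, 360)`;
#' saturation and value in `[0, 1]`.
#'
#' @param frame numeric array `c(h, w, 3)` with RGB in `[0, 1]` or `[0, 255]`.
#' @return numeric array `c(h, w, 3)` with channels hue, saturation, value.
#' @export
rgb_to_hsv_frame <- function(frame) {
  d <- dim(frame)
  stopifnot(length(d) == 3, d[3] == 3)
  mx <- max(frame)
  scale <- if (mx > 1) 255 else 1
  m <- rbind(
    as.vector(frame[, , 1]),
    as.vector(frame[, , 2]),
    as.vector(frame[, , 3])
  )
  hsv <- grDevices::rgb2hsv(m, maxColorValue = scale)
  out <- array(0, dim = d)
  out[, , 1] <- (hsv[1, ] * 360) %% 360
  out[, , 2] <- hsv[2, ]
  out[, , 3] <- hsv[3, ]
  out
}

#' Convert HSV channels to an RGB frame
#'
#' Vectorized inverse hexcone transform; used by the scene renderer.
#'
#' @param h hue in degrees, any numeric shape.
#' @param s,v saturation and value in `[0, 1]`, same shape as `h`.
#' @return array with one extra trailing dimension of size 3 (RGB in `[0, 1]`).
#' @export
hsv_to_rgb_frame <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
    ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
    ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
    ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  dd <- if (is.null(dim(h))) length(h) else dim(h)
  array(c(r, g, b), dim = c(dd, 3))
}

#' Write a frame to a PNG file
#' @param frame numeric array `c(h, w, 3)` in `[0, 1]`.
#' @param path output file.
#' @export
write_frame_png <- function(frame, path) {
  png::writePNG(pmin(pmax(frame, 0), 1), target = path)
  invisible(path)
}

#' Read a frame from a PNG file
#' @param path PNG file.
#' @return numeric array `c(h, w, 3)` in `[0, 1]`.
#' @export
read_frame_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) {
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  }
  img[, , 1:3, drop = FALSE]
}
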
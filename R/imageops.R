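#' Rotate a square image about its center
#'
#' Rotates the image counter-clockwise by `angle_deg` degrees about the
#' center pixel at (floor(m/2)+1, floor(m/2)+1) (1-based). The output grid
#' is filled by inverse-mapping with bilinear interpolation; samples that
#' fall outside the source image are zero.
#'
#' Angles are measured counter-clockwise as the image is displayed (row
#' index increasing downwards), which is also the direction of increasing
#' angle in [polar_resample()].
#'
#' @param img numeric m x m matrix (rows = y, columns = x).
#' @param angle_deg rotation angle in degrees; positive is counter-clockwise.
#' @return an m x m numeric matrix.
#' @seealso [shift_image()], [polar_resample()]
#' @examples
#' ph <- make_phantom(64, 6, seed = 1)
#' r <- rotate_image(ph, 30)
#' @export
rotate_image <- function(img, angle_deg) {
  assert_square_image(img)
  if (length(angle_deg) != 1L || !is.finite(angle_deg))
    stop("angle_deg must be a single finite number", call. = FALSE)
  if (angle_deg %% 360 == 0) return(img)
  m <- nrow(img)
  c0 <- floor(m / 2) + 1
  th <- angle_deg * pi / 180
  # output pixel (row = y, col = x) -> math coords (u, v) with v up
  u <- rep(seq_len(m) - c0, each = m)        # columns
  v <- rep.int(c0 - seq_len(m), m)           # rows vary fastest
  # inverse rotation of the sampling point
  us <- u * cos(th) + v * sin(th)
  vs <- -u * sin(th) + v * cos(th)
  vals <- .bilinear_sample(img, c0 - vs, c0 + us)
  matrix(vals, m, m)
}

# fft frequency index vector 0, 1, ..., then negative frequencies
fft_freq <- function(m) {
  c(0:floor(m / 2), seq_len(ceiling(m / 2) - 1) - ceiling(m / 2))
}

#' Shift a square image by a (possibly fractional) number of pixels
#'
#' Translates image content by `+dx` pixels along x (columns, rightward)
#' and `+dy` pixels along y (rows, downward) using Fourier phase
#' modulation. The shift is circular, and exact for band-limited content;
#' for integer shifts it reproduces index rolling of the pixel grid to
#' floating-point accuracy.
#'
#' @param img numeric m x m matrix.
#' @param dx,dy shift in pixels; may be fractional.
#' @return an m x m numeric matrix.
#' @seealso [rotate_image()]
#' @export
shift_image <- function(img, dx, dy) {
  assert_square_image(img)
  if (!is.finite(dx) || !is.finite(dy))
    stop("dx and dy must be finite", call. = FALSE)
  if (dx == 0 && dy == 0) return(img)
  m <- nrow(img)
  k <- fft_freq(m)
  px <- exp(-2i * pi * k * dx / m)   # columns (x)
  py <- exp(-2i * pi * k * dy / m)   # rows (y)
  if (m %% 2 == 0) {
    # keep the Nyquist component real so fractional shifts stay symmetric
    px[m / 2 + 1] <- cos(pi * dx)
    py[m / 2 + 1] <- cos(pi * dy)
  }
  ph <- outer(py, px)
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (m * m)
}

# polar sampling grid for side length m, cached: rows r = 1..floor(m/2),
# columns t = 0..359 degrees; returns list(row, col) of 1-based positions
polar_grid <- function(m) {
  key <- paste0("polar", m)
  g <- .cache[[key]]
  if (!is.null(g)) return(g)
  c0 <- floor(m / 2) + 1
  R <- floor(m / 2)
  r <- rep.int(seq_len(R), 360)
  t <- rep((0:359) * pi / 180, each = R)
  g <- list(row = c0 - r * sin(t), col = c0 + r * cos(t), R = R)
  .cache[[key]] <- g
  g
}

#' Resample a square image onto a polar grid
#'
#' Samples the image at radii 1..floor(m/2) pixels (rows) and angles
#' 0..359 degrees in one-degree steps (columns), measured
#' counter-clockwise from the +x axis about the center pixel
#' (floor(m/2)+1, floor(m/2)+1). Sampling is bilinear; positions outside
#' the image are zero. Rotating the input by t degrees circularly shifts
#' the columns of the result by t.
#'
#' @param img numeric m x m matrix with m >= 16.
#' @return a floor(m/2) x 360 numeric matrix.
#' @seealso [rotate_image()], [estimate_rotation()]
#' @export
polar_resample <- function(img) {
  assert_square_image(img, min_m = 16L)
  m <- nrow(img)
  g <- polar_grid(m)
  matrix(.bilinear_sample(img, g$row, g$col), g$R, 360)
}
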
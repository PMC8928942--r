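#' Polar Fourier spectrum of a square image
#'
#' Resamples the image onto the polar grid of [polar_resample()] and takes
#' its 2D FFT, giving a floor(m/2) x 360 complex spectrum in which an
#' in-plane rotation of the image appears as a circular shift along the
#' angular (column) axis.
#'
#' @param img numeric m x m matrix, m >= 16.
#' @return a floor(m/2) x 360 complex matrix.
#' @export
polar_spectrum <- function(img) {
  stats::fft(polar_resample(img))
}

# circular shift of rows by s positions (row i of the result is row i - s)
circshift_rows <- function(x, s) {
  nr <- nrow(x)
  x[((seq_len(nr) - 1 - s) %% nr) + 1, , drop = FALSE]
}

# fftshift along one axis: 0-based lag n lands at 1-based position
# ((n + floor(m/2)) mod m) + 1, so lag 0 maps to the center floor(m/2)+1
fftshift_index <- function(m) {
  f <- floor(m / 2)
  ((seq_len(m) - 1 - f) %% m) + 1
}

#' Rotational cross-correlation of two polar spectra
#'
#' Multiplies the first spectrum by the complex conjugate of the second,
#' takes the 2D inverse FFT and the absolute value, and circularly shifts
#' the rows by floor(m/4) positions to center the large values along the
#' radial axis. The column index of the peak encodes the rotation angle
#' between the source images (one degree per column).
#'
#' @param Fi,Fj complex floor(m/2) x 360 matrices from [polar_spectrum()]
#'   of two images with the same side length.
#' @return a floor(m/2) x 360 real matrix with attribute `centered = TRUE`.
#' @seealso [estimate_rotation()], [refine_peak()]
#' @export
rotation_cross_correlation <- function(Fi, Fj) {
  if (!is.complex(Fi) || !is.complex(Fj))
    stop("Fi and Fj must be complex spectra", call. = FALSE)
  if (nrow(Fi) != nrow(Fj) || ncol(Fi) != ncol(Fj))
    stop("spectrum shapes differ", call. = FALSE)
  C <- Mod(stats::fft(Fi * Conj(Fj), inverse = TRUE)) / length(Fi)
  C <- circshift_rows(C, nrow(C) %/% 2)  # floor(m/4) positions
  attr(C, "centered") <- TRUE
  attr(C, "axis") <- "rotation"
  C
}

#' Translational cross-correlation of two images
#'
#' Computes the inverse FFT of the product of the first image's spectrum
#' with the conjugate of the second's, keeps the real part (the imaginary
#' part is floating-point noise for real images), and recenters the matrix
#' so that zero displacement maps to the center position
#' (floor(m/2)+1, floor(m/2)+1). The peak position read through
#' [peak_to_shifts()] gives the displacement of `Mj` relative to `Mi`.
#'
#' @param Mi,Mj numeric m x m matrices of equal size.
#' @return an m x m real matrix with attribute `centered = TRUE`.
#' @seealso [estimate_shift()], [peak_to_shifts()]
#' @export
translation_cross_correlation <- function(Mi, Mj) {
  assert_square_image(Mi)
  assert_square_image(Mj)
  assert_same_size(Mi, Mj)
  m <- nrow(Mi)
  C <- Re(stats::fft(stats::fft(Mi) * Conj(stats::fft(Mj)),
                     inverse = TRUE)) / (m * m)
  idx <- fftshift_index(m)
  C <- C[idx, idx]
  attr(C, "centered") <- TRUE
  attr(C, "axis") <- "translation"
  C
}

# linear operator evaluating the interpolating cubic spline through n
# equally spaced samples at 0.1-unit steps; (10*(n-1)+1) x n, cached.
# Spline interpolation is linear in the sample values, so upsampling a
# patch reduces to two small matrix products.
spline_upsample_operator <- function(n) {
  key <- paste0("spl", n)
  B <- .cache[[key]]
  if (!is.null(B)) return(B)
  xout <- seq(1, n, by = 0.1)
  B <- matrix(0, length(xout), n)
  for (j in seq_len(n)) {
    e <- numeric(n)
    e[j] <- 1
    B[, j] <- stats::spline(seq_len(n), e, xout = xout, method = "fmm")$y
  }
  .cache[[key]] <- B
  B
}

# integer argmax with ties broken by smallest row, then smallest column
argmax_rc <- function(x) {
  idx <- which(x == max(x))
  rows <- ((idx - 1) %% nrow(x)) + 1
  cols <- ((idx - 1) %/% nrow(x)) + 1
  o <- order(rows, cols)[1]
  c(rows[o], cols[o])
}

#' Refine a correlation peak by 2D spline interpolation
#'
#' Extracts a `window` x `window` patch centered on the integer argmax of
#' the correlation matrix, interpolates it onto a grid with 0.1-unit steps
#' (an 11-point window becomes 101 x 101) with a separable cubic spline,
#' and returns the real-valued position of the interpolated maximum. On
#' the angular axis of a rotational correlation matrix the window wraps
#' circularly (`wrap_cols = TRUE`); on all other axes the window slides
#' inward at the matrix edge so it stays on-grid.
#'
#' The refined position always lies within 0.5 grid units of the coarse
#' integer peak in each axis; a flat (constant) patch returns the coarse
#' peak with `flat = TRUE`.
#'
#' @param C real correlation matrix (from [rotation_cross_correlation()]
#'   or [translation_cross_correlation()]).
#' @param window odd patch size (default 11).
#' @param wrap_cols should the column axis wrap circularly?
#' @return a list with elements `row`, `col` (refined 1-based position;
#'   `col` may need reduction modulo the column count when the window
#'   wrapped), `patch` (the interpolated surface), `flat`, and the coarse
#'   peak `coarse_row`, `coarse_col`.
#' @export
refine_peak <- function(C, window = 11L, wrap_cols = FALSE) {
  if (window %% 2 != 1) stop("window must be odd", call. = FALSE)
  nr <- nrow(C)
  nc <- ncol(C)
  pk <- argmax_rc(C)
  pr <- pk[1]
  pc <- pk[2]
  h <- (window - 1L) %/% 2L

  wr <- min(window, nr)                     # row window, clamped to grid
  rstart <- min(max(pr - (wr - 1L) %/% 2L, 1L), nr - wr + 1L)
  ridx <- rstart + 0:(wr - 1L)

  if (wrap_cols) {
    wc <- min(window, nc)
    cstart <- pc - (wc - 1L) %/% 2L         # may run off the edge; wraps
    cidx <- ((cstart - 1L + 0:(wc - 1L)) %% nc) + 1L
  } else {
    wc <- min(window, nc)
    cstart <- min(max(pc - (wc - 1L) %/% 2L, 1L), nc - wc + 1L)
    cidx <- cstart + 0:(wc - 1L)
  }

  patch <- C[ridx, cidx, drop = FALSE]
  if (max(patch) - min(patch) == 0) {
    return(list(row = as.numeric(pr), col = as.numeric(pc), patch = patch,
                flat = TRUE, coarse_row = pr, coarse_col = pc))
  }

  Br <- spline_upsample_operator(wr)
  Bc <- spline_upsample_operator(wc)
  U <- Br %*% patch %*% t(Bc)

  upk <- argmax_rc(U)
  row <- rstart + (upk[1] - 1) / 10
  col <- cstart + (upk[2] - 1) / 10
  # the subgrid peak must stay within half a grid unit of the integer peak;
  # if spline overshoot puts the global interpolated maximum further away,
  # restrict the search to the half-unit neighborhood of the coarse peak
  if (abs(row - pr) > 0.5 + 1e-9 || abs(col - pc) > 0.5 + 1e-9) {
    rr <- which(abs(rstart + (seq_len(nrow(U)) - 1) / 10 - pr) <= 0.5 + 1e-9)
    cc <- which(abs(cstart + (seq_len(ncol(U)) - 1) / 10 - pc) <= 0.5 + 1e-9)
    sub <- U[rr, cc, drop = FALSE]
    spk <- argmax_rc(sub)
    row <- rstart + (rr[spk[1]] - 1) / 10
    col <- cstart + (cc[spk[2]] - 1) / 10
  }
  list(row = row, col = col, patch = U, flat = FALSE,
       coarse_row = pr, coarse_col = pc)
}

#' Fold a raw angle into the signed rotation range
#'
#' Maps a raw peak angle in `[0, 360)` degrees onto the signed range
#' `[-180, 180]`: angles up to 180 are kept, angles above 180 have 360
#' subtracted.
#'
#' @param raw_deg angle in degrees, `0 <= raw_deg < 360`.
#' @return angle in degrees in `[-180, 180]`.
#' @export
correct_angle <- function(raw_deg) {
  if (!is.finite(raw_deg) || raw_deg < 0 || raw_deg >= 360)
    stop("raw angle must lie in [0, 360)", call. = FALSE)
  if (raw_deg <= 180) raw_deg else raw_deg - 360
}

#' Convert a correlation peak position to displacements
#'
#' Applies the center convention of the recentered translational
#' correlation matrix: `dx = floor(m/2) - x + 1`, `dy = floor(m/2) - y + 1`,
#' so that a peak at the center position (floor(m/2)+1 on each axis) maps
#' to zero displacement. The result is the displacement of the test image
#' relative to the reference (the shift that was applied to produce it).
#'
#' @param x,y refined 1-based peak position (column, row).
#' @param m image side length in pixels.
#' @return named numeric vector `c(dx, dy)` in pixels.
#' @export
peak_to_shifts <- function(x, y, m) {
  c(dx = floor(m / 2) - x + 1, dy = floor(m / 2) - y + 1)
}

assert_nonflat <- function(img, what = "image") {
  if (stats::sd(img) == 0)
    stop(sprintf("%s is constant; alignment peak is undefined", what),
         call. = FALSE)
  invisible(NULL)
}

#' Estimate the rotation angle between two images
#'
#' Frequency-domain rotational alignment: both images are transformed to
#' polar Fourier spectra, cross-correlated, and the angular position of
#' the correlation peak is read off. With `interpolate = TRUE` the peak is
#' refined by [refine_peak()] to 0.1-degree resolution; otherwise the
#' estimate is an integer number of degrees.
#'
#' @param Mi reference image (numeric m x m matrix).
#' @param Mj test image of the same size.
#' @param interpolate refine the peak by 2D spline interpolation?
#' @return the rotation angle in degrees in `[-180, 180]` such that
#'   `rotate_image(Mj, angle)` best matches `Mi`.
#' @examples
#' ph <- make_phantom(64, 6, seed = 1)
#' estimate_rotation(ph, rotate_image(ph, -30))  # ~ +30
#' @export
estimate_rotation <- function(Mi, Mj, interpolate = TRUE) {
  assert_square_image(Mi, min_m = 16L)
  assert_square_image(Mj, min_m = 16L)
  assert_same_size(Mi, Mj)
  assert_nonflat(Mi, "reference image")
  assert_nonflat(Mj, "test image")
  rotation_from_spectrum(polar_spectrum(Mi), Mj, interpolate)
}

# rotation correction given the precomputed polar spectrum of the reference
rotation_from_spectrum <- function(Fi, Mj, interpolate) {
  C <- rotation_cross_correlation(Fi, polar_spectrum(Mj))
  if (interpolate) {
    pk <- refine_peak(C, wrap_cols = TRUE)
    raw <- round(pk$col - 1, 1) %% 360
  } else {
    raw <- (argmax_rc(C)[2] - 1) %% 360
  }
  correct_angle(raw)
}

#' Estimate the translational shift between two images
#'
#' Frequency-domain translational alignment: the images are
#' cross-correlated via their FFTs, the correlation matrix is recentered,
#' and the peak position is converted to pixel displacements. With
#' `interpolate = TRUE` the peak is refined by [refine_peak()] to
#' 0.1-pixel resolution; otherwise the estimates are integers.
#'
#' @param Mi reference image (numeric m x m matrix).
#' @param Mj test image of the same size.
#' @param interpolate refine the peak by 2D spline interpolation?
#' @return named numeric vector `c(dx, dy)` in pixels such that
#'   `shift_image(Mj, dx, dy)` best matches `Mi`.
#' @examples
#' ph <- make_phantom(64, 6, seed = 1)
#' estimate_shift(ph, shift_image(ph, -3.4, 2.1))  # ~ (3.4, -2.1)
#' @export
estimate_shift <- function(Mi, Mj, interpolate = TRUE) {
  assert_square_image(Mi)
  assert_square_image(Mj)
  assert_same_size(Mi, Mj)
  assert_nonflat(Mi, "reference image")
  assert_nonflat(Mj, "test image")
  shift_from_spectrum(stats::fft(Mi), Mj, interpolate)
}

# shift correction given the precomputed FFT of the reference
shift_from_spectrum <- function(Fi, Mj, interpolate) {
  m <- nrow(Mj)
  C <- Re(stats::fft(Fi * Conj(stats::fft(Mj)), inverse = TRUE)) / (m * m)
  idx <- fftshift_index(m)
  C <- C[idx, idx]
  if (interpolate) {
    pk <- refine_peak(C, wrap_cols = FALSE)
    x <- pk$col
    y <- pk$row
  } else {
    pk <- argmax_rc(C)
    x <- pk[2]
    y <- pk[1]
  }
  d <- peak_to_shifts(x, y, m)   # displacement of Mj relative to Mi
  corr <- -d                     # correction that maps Mj back onto Mi
  if (interpolate) corr <- round(corr, 1)
  c(dx = unname(corr[1]), dy = unname(corr[2]))
}

# rotation of a displacement vector (dx, dy) in image coordinates
# (x right, y down) by a counter-clockwise angle, matching rotate_image
rotate_displacement <- function(d, angle_deg) {
  th <- angle_deg * pi / 180
  c(d[1] * cos(th) + d[2] * sin(th),
    -d[1] * sin(th) + d[2] * cos(th))
}

#' Jointly align a test image onto a reference
#'
#' Alternates rotational and translational frequency-domain alignment: at
#' each iteration the working image is rotationally aligned to the
#' reference, rotated, translationally aligned, and shifted. Increments
#' are accumulated so that a single final composition
#' `shift_image(rotate_image(M, theta), dx, dy)` applied to the
#' *original* test image reproduces the iteratively warped image,
#' avoiding accumulation of interpolation error. Iteration stops early
#' when the alignment parameters stop changing: either all increments of
#' the current iteration are zero (at the 0.1-unit output resolution this
#' is exact), or they are identical to those of the previous iteration.
#'
#' @param ref reference image (numeric m x m matrix).
#' @param img test image of the same size.
#' @param max_iter maximum number of iterations (default 10).
#' @param interpolate use spline peak refinement (0.1 deg / 0.1 px
#'   resolution)? Otherwise estimates are integers.
#' @param tol increments changing by less than this between consecutive
#'   iterations count as "unchanged".
#' @return an object of class `"cryo_alignment"`: a list with `theta`
#'   (degrees in `[-180, 180]`), `dx`, `dy` (pixels), `n_iter`,
#'   `converged`, `aligned` (the final aligned image computed from the
#'   original input), and the similarity to the reference before and
#'   after alignment (`corr_before`, `corr_after`).
#' @examples
#' ph <- make_phantom(64, 6, seed = 1)
#' test <- perturb(ph, theta = 25, dx = 2, dy = -1.5)
#' fit <- align_images(ph, test)
#' coef(fit)
#' @export
align_images <- function(ref, img, max_iter = 10L, interpolate = TRUE,
                         tol = 1e-6) {
  if (max_iter < 1) stop("max_iter must be at least 1", call. = FALSE)
  assert_square_image(ref, min_m = 16L)
  assert_square_image(img, min_m = 16L)
  assert_same_size(ref, img)

  assert_nonflat(ref, "reference image")
  assert_nonflat(img, "test image")
  Fi_rot <- polar_spectrum(ref)   # reference spectra computed once
  Fi_tr <- stats::fft(ref)

  W <- img
  theta <- 0
  shift <- c(0, 0)
  prev <- c(NA_real_, NA_real_, NA_real_)
  n_iter <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    n_iter <- it
    dth <- rotation_from_spectrum(Fi_rot, W, interpolate)
    W <- rotate_image(W, dth)
    ds <- shift_from_spectrum(Fi_tr, W, interpolate)
    W <- shift_image(W, ds[1], ds[2])
    # accumulated transform: W = shift(rotate(img, theta), shift);
    # rotating W by dth rotates the running displacement vector too
    theta <- theta + dth
    shift <- rotate_displacement(shift, dth) + ds
    cur <- c(dth, ds)
    # the accumulated parameters stop changing when the increments reach
    # zero; a repeated nonzero increment also cannot improve the estimate
    if (all(abs(cur) < tol) ||
        (all(is.finite(prev)) && all(abs(cur - prev) < tol))) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  theta <- ((theta + 180) %% 360) - 180
  if (theta == -180) theta <- 180
  aligned <- shift_image(rotate_image(img, theta), shift[1], shift[2])
  out <- list(theta = theta, dx = unname(shift[1]), dy = unname(shift[2]),
              n_iter = n_iter, converged = converged, aligned = aligned,
              interpolate = interpolate,
              corr_before = image_similarity(ref, img),
              corr_after = image_similarity(ref, aligned),
              call = match.call())
  class(out) <- "cryo_alignment"
  out
}

#' @export
print.cryo_alignment <- function(x, ...) {
  cat("Frequency-domain image alignment",
      if (x$interpolate) "(spline-refined)" else "(integer grid)", "\n")
  cat(sprintf("  rotation: %8.1f deg\n", x$theta))
  cat(sprintf("  shift:    (%.1f, %.1f) px\n", x$dx, x$dy))
  cat(sprintf("  iterations: %d (%s)\n", x$n_iter,
              if (x$converged) "converged" else "max iterations reached"))
  cat(sprintf("  similarity to reference: %.4f -> %.4f\n",
              x$corr_before, x$corr_after))
  invisible(x)
}

#' @export
coef.cryo_alignment <- function(object, ...) {
  c(theta = object$theta, dx = object$dx, dy = object$dy)
}
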
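#' Seeded structured phantom image
#'
#' A rotationally asymmetric test image standing in for a natural test
#' image: `n_blobs` randomly placed anisotropic 2D Gaussian blobs plus a
#' dense layer of small faint Gaussians (fine texture at all radii and
#' orientations, which natural images have and which keeps the rotational
#' correlation peak sharp under residual shifts), over a gentle intensity
#' gradient, tapered by a radial raised-cosine mask so all content sits
#' well inside the inscribed disc. The mask keeps planted rotations and
#' shifts (up to the m/10 range used in the benchmarks) exactly
#' invertible: nothing is clipped at the frame edge or lost in the
#' corners.
#'
#' @param m side length in pixels (at least 64).
#' @param n_blobs number of primary Gaussian blobs (at least 5); the fine
#'   texture layer contains `20 * n_blobs` additional small Gaussians.
#' @param seed integer seed; the image is bit-reproducible given
#'   `(m, n_blobs, seed)`.
#' @return a numeric m x m matrix.
#' @examples
#' ph <- make_phantom(128, 10, seed = 3)
#' @export
make_phantom <- function(m = 256L, n_blobs = 12L, seed = 0L) {
  if (m < 64) stop("m must be at least 64", call. = FALSE)
  if (n_blobs < 5) stop("n_blobs must be at least 5", call. = FALSE)
  with_seed(seed, {
    c0 <- floor(m / 2) + 1
    x <- matrix(rep(seq_len(m) - c0, each = m), m, m)   # columns
    y <- matrix(rep(seq_len(m) - c0, times = m), m, m)  # rows
    # weak gradient background; kept small so the rotationally symmetric
    # part of the image (background x radial mask) stays a minor component
    img <- 0.05 * (x + y) / m + 0.05
    add_blobs <- function(img, n, s_lo, s_hi, a_lo, a_hi) {
      for (b in seq_len(n)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- 0.28 * m * sqrt(stats::runif(1))   # uniform over the disc
        cx <- rad * cos(ang)
        cy <- rad * sin(ang)
        s1 <- stats::runif(1, s_lo, s_hi)
        s2 <- stats::runif(1, s_lo, s_hi)
        phi <- stats::runif(1, 0, pi)
        amp <- stats::runif(1, a_lo, a_hi)
        u <- (x - cx) * cos(phi) + (y - cy) * sin(phi)
        v <- -(x - cx) * sin(phi) + (y - cy) * cos(phi)
        img <- img + amp * exp(-0.5 * (u / s1)^2 - 0.5 * (v / s2)^2)
      }
      img
    }
    img <- add_blobs(img, n_blobs, m / 64, m / 24, 0.5, 1.5)
    # fine-texture layer: many small faint blobs (width floored at the
    # pixel scale) so the image has structure at all radii and orientations
    img <- add_blobs(img, 20L * n_blobs, max(m / 144, 0.7), max(m / 48, 1.4),
                     0.2, 0.6)
    # radial raised-cosine taper: 1 inside 0.30 m, 0 outside 0.38 m
    r <- sqrt(x^2 + y^2)
    r1 <- 0.30 * m
    r2 <- 0.38 * m
    w <- ifelse(r <= r1, 1,
                ifelse(r >= r2, 0, 0.5 * (1 + cos(pi * (r - r1) / (r2 - r1)))))
    img * w
  })
}

#' Synthetic 3D density as a Gaussian mixture
#'
#' A seeded anisotropic 3D Gaussian mixture standing in for a single
#' asymmetric macromolecule, used to generate projection images
#' analytically. It is a synthetic stand-in, not derived from any
#' deposited map.
#'
#' @param n_blobs number of mixture components.
#' @param m nominal grid side in pixels; component centers are drawn
#'   within 0.2 m of the origin and widths within `[m/24, m/10]`.
#' @param seed integer seed.
#' @return a list of class `"synthetic_volume"` with per-component
#'   `centers` (n x 3), `widths` (n x 3 axis standard deviations),
#'   `axes` (list of 3 x 3 orientation matrices), `amplitudes`, and `m`.
#' @export
make_volume <- function(n_blobs = 8L, m = 64L, seed = 0L) {
  with_seed(seed, {
    centers <- matrix(stats::runif(3 * n_blobs, -0.2 * m, 0.2 * m),
                      n_blobs, 3)
    widths <- matrix(stats::runif(3 * n_blobs, m / 24, m / 10), n_blobs, 3)
    axes <- lapply(seq_len(n_blobs), function(i) random_rotations(1, seed = NULL)[[1]])
    amplitudes <- stats::runif(n_blobs, 0.5, 1.5)
    structure(list(centers = centers, widths = widths, axes = axes,
                   amplitudes = amplitudes, m = m),
              class = "synthetic_volume")
  })
}

#' Uniformly distributed random rotation matrices
#'
#' Draws rotations uniformly over SO(3) via normalized quaternions built
#' from four standard normal deviates.
#'
#' @param n number of rotations.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return a list of `n` orthonormal 3 x 3 matrices with determinant +1.
#' @export
random_rotations <- function(n, seed = 0L) {
  draw <- function() {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  if (is.null(seed)) replicate(n, draw(), simplify = FALSE)
  else with_seed(seed, replicate(n, draw(), simplify = FALSE))
}

#' Analytic projections of a Gaussian-mixture volume
#'
#' For each viewing rotation the volume is rotated and integrated along
#' the z (viewing) axis. A rotated 3D Gaussian projects to a 2D Gaussian,
#' so the line integrals are evaluated in closed form on the m x m pixel
#' grid: for each component with rotated covariance partitioned into the
#' in-plane block A, cross term b and viewing variance c, the projection
#' is a 2D Gaussian with covariance A and mass `a * (2 pi)^{3/2}
#' sqrt(det Sigma)`.
#'
#' @param vol a `"synthetic_volume"` from [make_volume()].
#' @param rotations list of 3 x 3 rotation matrices (orthonormal,
#'   determinant +1), e.g. from [random_rotations()].
#' @param m output image side in pixels (default `vol$m`).
#' @return a list of numeric m x m matrices, one per rotation.
#' @export
project_volume <- function(vol, rotations, m = vol$m) {
  if (!inherits(vol, "synthetic_volume"))
    stop("vol must come from make_volume()", call. = FALSE)
  check_rot <- function(R) {
    if (!is.matrix(R) || any(dim(R) != 3) ||
        max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8)
      stop("rotations must be orthonormal with determinant +1", call. = FALSE)
  }
  lapply(rotations, check_rot)
  c0 <- floor(m / 2) + 1
  # math coords: u right, v up
  u <- matrix(rep(seq_len(m) - c0, each = m), m, m)
  v <- matrix(rep(c0 - seq_len(m), times = m), m, m)
  nb <- nrow(vol$centers)
  lapply(rotations, function(R) {
    img <- matrix(0, m, m)
    for (i in seq_len(nb)) {
      A <- vol$axes[[i]]
      Sig <- A %*% diag(vol$widths[i, ]^2) %*% t(A)
      SigR <- R %*% Sig %*% t(R)
      mu <- as.vector(R %*% vol$centers[i, ])
      A2 <- SigR[1:2, 1:2]
      mass <- vol$amplitudes[i] * (2 * pi)^1.5 * sqrt(det(Sig))
      amp2 <- mass / (2 * pi * sqrt(det(A2)))
      P <- solve(A2)
      du <- u - mu[1]
      dv <- v - mu[2]
      q <- P[1, 1] * du^2 + 2 * P[1, 2] * du * dv + P[2, 2] * dv^2
      img <- img + amp2 * exp(-0.5 * q)
    }
    img
  })
}

#' Apply a planted shift-then-rotate perturbation
#'
#' Shifts the image first and rotates it second, the order used to
#' generate joint-alignment test images; the exact inverse is
#' `shift_image(rotate_image(out, -theta), -dx, -dy)`.
#'
#' @param img numeric m x m matrix.
#' @param theta rotation in degrees (counter-clockwise).
#' @param dx,dy shift in pixels applied before the rotation.
#' @return a numeric m x m matrix.
#' @export
perturb <- function(img, theta, dx, dy) {
  rotate_image(shift_image(img, dx, dy), theta)
}

#' Add Gaussian noise at a prescribed signal-to-noise ratio
#'
#' Adds zero-mean white Gaussian noise with variance `var(img) / snr`,
#' following the definition SNR = var(signal) / var(noise); at SNR 0.1
#' the noise variance is ten times the clean-image variance.
#'
#' @param img numeric m x m matrix with nonzero variance.
#' @param snr target signal-to-noise ratio (> 0).
#' @param seed integer seed; the noise field is reproducible given
#'   `(seed, dim)`.
#' @return a numeric m x m matrix.
#' @export
add_noise <- function(img, snr, seed = 0L) {
  assert_square_image(img)
  if (!is.finite(snr) || snr <= 0) stop("snr must be positive", call. = FALSE)
  v <- stats::var(as.vector(img))
  if (v == 0) stop("image is constant; SNR is undefined", call. = FALSE)
  with_seed(seed, img + matrix(stats::rnorm(length(img),
                                            sd = sqrt(v / snr)),
                               nrow(img), ncol(img)))
}

#' Planted-view projection stack
#'
#' Generates a noisy particle stack with a known class structure:
#' `views` projection directions are taken far apart on SO(3), and each
#' clean view is replicated `per_view` times under a random one-decimal
#' in-plane rotation in `[-180, 180]` degrees and a one-decimal shift in
#' `[-m/20, m/20]` pixels, then corrupted with Gaussian noise at `snr`.
#'
#' @param views number of distinct projection directions (2 to 6).
#' @param per_view copies per view.
#' @param snr signal-to-noise ratio of the additive noise.
#' @param m image side in pixels.
#' @param seed integer seed.
#' @return a list with `images` (list of length `views * per_view`),
#'   `labels` (generating view of each image), `clean` (the clean view
#'   images), and `truth` (data frame of planted theta/dx/dy).
#' @export
make_class_stack <- function(views = 3L, per_view = 30L, snr = 0.5,
                             m = 64L, seed = 0L) {
  if (views < 2 || views > 6)
    stop("views must be between 2 and 6", call. = FALSE)
  # well-separated fixed directions: identity plus 90-degree tilts
  base <- list(
    diag(3),
    matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE),   # +90 about x
    matrix(c(0, 0, 1, 0, 1, 0, -1, 0, 0), 3, 3, byrow = TRUE),   # +90 about y
    matrix(c(1, 0, 0, 0, -1, 0, 0, 0, -1), 3, 3, byrow = TRUE),  # 180 about x
    matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3, byrow = TRUE),   # -90 about y
    matrix(c(1, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3, byrow = TRUE)    # -90 about x
  )
  vol <- make_volume(n_blobs = 8L, m = m, seed = seed)
  clean <- project_volume(vol, base[seq_len(views)], m = m)
  n <- views * per_view
  truth <- with_seed(seed + 1L, data.frame(
    view = rep(seq_len(views), each = per_view),
    theta = round(stats::runif(n, -180, 180), 1),
    dx = round(stats::runif(n, -m / 20, m / 20), 1),
    dy = round(stats::runif(n, -m / 20, m / 20), 1)))
  images <- vector("list", n)
  for (i in seq_len(n)) {
    im <- perturb(clean[[truth$view[i]]], truth$theta[i],
                  truth$dx[i], truth$dy[i])
    images[[i]] <- add_noise(im, snr, seed = seed + 1000L + i)
  }
  list(images = images, labels = truth$view, clean = clean, truth = truth)
}
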
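# shared fixtures and independent brute-force oracles for the alignment tests

# boolean mask of the disc of radius frac*m about the image center
disc_mask <- function(m, frac = 0.45) {
  c0 <- floor(m / 2) + 1
  x <- matrix(rep(seq_len(m) - c0, each = m), m, m)
  y <- matrix(rep(seq_len(m) - c0, times = m), m, m)
  sqrt(x^2 + y^2) <= frac * m
}

# circular integer roll with the shift_image convention: out(x) = in(x - dx)
roll2 <- function(img, dx, dy) {
  m <- nrow(img)
  ri <- ((seq_len(m) - 1 - dy) %% m) + 1
  ci <- ((seq_len(m) - 1 - dx) %% m) + 1
  img[ri, ci]
}

# exhaustive real-space rotation search at 1-degree steps: the integer
# correction angle whose application maximizes masked correlation with ref
oracle_rotation <- function(ref, test) {
  m <- nrow(ref)
  mask <- disc_mask(m)
  best <- -Inf
  best_a <- NA_integer_
  for (a in -179:180) {
    r <- rotate_image(test, a)
    s <- stats::cor(ref[mask], r[mask])
    if (s > best) {
      best <- s
      best_a <- a
    }
  }
  best_a
}

# exhaustive integer-shift search over [-lim, lim]^2: the correction
# (dx, dy) whose application maximizes full-frame correlation with ref
oracle_shift <- function(ref, test, lim) {
  best <- -Inf
  best_d <- c(NA_integer_, NA_integer_)
  for (dx in -lim:lim) {
    for (dy in -lim:lim) {
      s <- stats::cor(as.vector(ref), as.vector(roll2(test, dx, dy)))
      if (s > best) {
        best <- s
        best_d <- c(dx, dy)
      }
    }
  }
  best_d
}

# smooth radially symmetric test image (2D Gaussian at the image center)
radial_gaussian <- function(m, sigma = m / 8) {
  c0 <- floor(m / 2) + 1
  x <- matrix(rep(seq_len(m) - c0, each = m), m, m)
  y <- matrix(rep(seq_len(m) - c0, times = m), m, m)
  exp(-(x^2 + y^2) / (2 * sigma^2))
}
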
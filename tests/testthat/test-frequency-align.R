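test_that("rotational cross-correlation peaks at the planted rotation", {
  ph <- make_phantom(128, 8, seed = 1)
  Fi <- polar_spectrum(ph)
  expect_equal(dim(Fi), c(64, 360))

  # self-correlation: peak column encodes zero rotation
  C <- rotation_cross_correlation(Fi, Fi)
  expect_equal(dim(C), c(64, 360))
  expect_true(all(C >= 0))
  pc <- unname(which(C == max(C), arr.ind = TRUE)[1, 2])
  expect_equal(correct_angle(pc - 1), 0)

  # planted 30-degree rotation: coarse peak within one column of the
  # brute-force real-space search result
  Mj <- rotate_image(ph, 30)
  C2 <- rotation_cross_correlation(Fi, polar_spectrum(Mj))
  pc2 <- which(C2 == max(C2), arr.ind = TRUE)[1, 2]
  coarse <- correct_angle((pc2 - 1) %% 360)
  expect_lte(abs(coarse - oracle_rotation(ph, Mj)), 1)
  expect_lte(abs(coarse - (-30)), 1)

  expect_error(rotation_cross_correlation(Fi, Fi[1:32, ]), "shape")
})

test_that("translational cross-correlation peaks at the planted displacement", {
  ph <- make_phantom(128, 8, seed = 2)
  C <- translation_cross_correlation(ph, ph)
  expect_equal(dim(C), c(128, 128))
  pk <- which(C == max(C), arr.ind = TRUE)[1, ]
  d <- peak_to_shifts(pk[2], pk[1], 128)
  expect_equal(unname(d), c(0, 0))

  # planted integer shift: Eq-style readout returns the displacement itself
  Mj <- shift_image(ph, 5, -3)
  C2 <- translation_cross_correlation(ph, Mj)
  pk2 <- which(C2 == max(C2), arr.ind = TRUE)[1, ]
  d2 <- peak_to_shifts(pk2[2], pk2[1], 128)
  expect_equal(unname(d2), c(5, -3))

  expect_error(translation_cross_correlation(ph, ph[1:64, 1:64]), "identical size")
})

test_that("angle folding and peak-to-shift conversion follow the conventions", {
  expect_equal(correct_angle(350), -10)
  expect_equal(correct_angle(180), 180)
  expect_equal(correct_angle(0), 0)
  expect_equal(correct_angle(180.1), -179.9)
  expect_error(correct_angle(360), "\\[0, 360\\)")
  expect_error(correct_angle(-0.1), "\\[0, 360\\)")

  expect_equal(unname(peak_to_shifts(65, 65, 128)), c(0, 0))
  expect_equal(unname(peak_to_shifts(60, 70, 128)), c(5, -5))
  expect_equal(unname(peak_to_shifts(64.7, 65, 128))[1], 0.3)
})

test_that("spline peak refinement matches a dense-evaluation oracle", {
  # on-node quadratic peak: refinement must return the integer peak
  x <- 1:21
  Cq <- -outer((x - 11)^2, (x - 11)^2, `+`)
  pk <- refine_peak(Cq)
  expect_equal(pk$row, 11)
  expect_equal(pk$col, 11)
  expect_gte(max(pk$patch), max(Cq))

  # Gaussian bump centered off-node at (r0 + 0.3, c0 - 0.2)
  r0 <- 11; c0 <- 12
  Cg <- exp(-(outer((x - (r0 + 0.3))^2, (x - (c0 - 0.2))^2, `+`)) / 18)
  pk2 <- refine_peak(Cg)
  # independent oracle: same separable cubic spline on the same 11x11
  # patch, evaluated densely at 0.001 steps along each axis through the
  # refined neighborhood
  patch <- Cg[(r0 - 5):(r0 + 5), (c0 - 5):(c0 + 5)]
  dense_max <- function(vals) {
    f <- stats::splinefun(1:11, vals, method = "fmm")
    xs <- seq(1, 11, by = 0.001)
    xs[which.max(f(xs))]
  }
  # profile through the peak row/column (separable surface)
  or_col <- dense_max(patch[6, ]) + (c0 - 6)
  or_row <- dense_max(patch[, 6]) + (r0 - 6)
  expect_lt(abs(pk2$row - or_row), 0.05 + 1e-9)
  expect_lt(abs(pk2$col - or_col), 0.05 + 1e-9)
  expect_lt(abs(pk2$row - (r0 + 0.3)), 0.05 + 1e-9)
  expect_lt(abs(pk2$col - (c0 - 0.2)), 0.05 + 1e-9)

  # refined peak stays within half a grid unit of the coarse peak
  expect_lte(abs(pk2$row - pk2$coarse_row), 0.5)
  expect_lte(abs(pk2$col - pk2$coarse_col), 0.5)

  # degenerate flat patch falls back to the coarse peak and says so
  flatC <- matrix(1, 21, 21)
  pkf <- refine_peak(flatC)
  expect_true(pkf$flat)
  expect_equal(c(pkf$row, pkf$col), c(pkf$coarse_row, pkf$coarse_col))

  expect_error(refine_peak(Cq, window = 10), "odd")
})

test_that("refinement window wraps on the angular axis", {
  ph <- make_phantom(128, 8, seed = 3)
  # planted rotation near 0 puts the correlation peak at the column seam
  Mj <- rotate_image(ph, -0.4)
  est <- estimate_rotation(ph, Mj)
  expect_lt(abs(est - 0.4), 0.5)
})

test_that("rotation estimates recover planted angles to subdegree accuracy", {
  ph <- make_phantom(256, 12, seed = 0)
  expect_equal(estimate_rotation(ph, ph), 0)
  Mj <- rotate_image(ph, -37.4)
  est <- estimate_rotation(ph, Mj)
  expect_lt(abs(est - 37.4), 0.5)
  # spline-refined estimates live on the 0.1-degree grid
  expect_equal(est * 10, round(est * 10))
  # integer-grid variant agrees with the exhaustive real-space search
  phs <- make_phantom(64, 8, seed = 1)
  Mk <- rotate_image(phs, 23)
  expect_equal(estimate_rotation(phs, Mk, interpolate = FALSE),
               oracle_rotation(phs, Mk))
  expect_error(estimate_rotation(matrix(1, 64, 64), phs), "constant")
})

test_that("rotation estimation is antisymmetric on noiseless phantoms", {
  ph <- make_phantom(128, 8, seed = 7)
  for (ang in c(15.3, -48.9, 101.2)) {
    A <- rotate_image(ph, ang / 2)
    B <- rotate_image(ph, -ang / 2)
    ab <- estimate_rotation(A, B)
    ba <- estimate_rotation(B, A)
    expect_lt(abs(((ab + ba + 180) %% 360) - 180), 0.2)
  }
})

test_that("shift estimates recover planted subpixel shifts", {
  ph <- make_phantom(256, 12, seed = 0)
  expect_equal(unname(estimate_shift(ph, ph)), c(0, 0))
  Mj <- shift_image(ph, -4.3, 8.1)
  est <- estimate_shift(ph, Mj)
  expect_lt(abs(est["dx"] - 4.3), 0.5)
  expect_lt(abs(est["dy"] - (-8.1)), 0.5)
  expect_equal(unname(est * 10), round(unname(est * 10)))
  # integer-grid variant equals the exhaustive roll search
  phs <- make_phantom(64, 8, seed = 2)
  Mk <- shift_image(phs, 4, -6)
  expect_equal(unname(estimate_shift(phs, Mk, interpolate = FALSE)),
               oracle_shift(phs, Mk, lim = 8))
  expect_error(estimate_shift(ph, matrix(2, 256, 256)), "constant")
})
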
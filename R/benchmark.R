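# absolute angular difference on the circle, in degrees
angular_error <- function(est, truth) {
  abs(((est - truth + 180) %% 360) - 180)
}

# frequency table of absolute errors with the standard bins
bin_errors <- function(err) {
  c("[0, 0.5)" = sum(err < 0.5),
    "[0.5, 1]" = sum(err >= 0.5 & err <= 1),
    "(1, 5]" = sum(err > 1 & err <= 5),
    "> 5" = sum(err > 5))
}

#' Planted-transform alignment benchmark
#'
#' Runs repeated alignment trials with known ground truth on a structured
#' image. Three modes mirror the standard protocol: `"rotation"` draws
#' one-decimal angles uniformly in `[-180, 180]` degrees and estimates
#' them with [estimate_rotation()]; `"shift"` draws one-decimal shifts in
#' `[-m/10, m/10]` pixels and estimates them with [estimate_shift()];
#' `"both"` first shifts by one-decimal offsets in `[-m/20, m/20]`, then
#' rotates, and recovers all three parameters with [align_images()]
#' (maximum 10 iterations).
#'
#' @param mode one of `"rotation"`, `"shift"`, `"both"`.
#' @param image reference image; defaults to `make_phantom(m, 12, seed)`.
#' @param m side length of the default phantom.
#' @param n_trials number of trials (default 100).
#' @param interpolate use spline peak refinement (0.1 resolution)?
#' @param seed integer seed; the phantom uses `seed`, the planted
#'   parameters use `seed + 1`.
#' @param max_iter maximum joint-alignment iterations.
#' @return a data frame of class `"alignment_benchmark"` with one row per
#'   trial: the planted `true_theta`/`true_dx`/`true_dy`, the estimates,
#'   absolute errors, and `n_iter`. Attributes record the mode and
#'   settings.
#' @examples
#' b <- alignment_benchmark("rotation", m = 128, n_trials = 5, seed = 1)
#' summary(b)
#' @export
alignment_benchmark <- function(mode = c("rotation", "shift", "both"),
                                image = NULL, m = 256L, n_trials = 100L,
                                interpolate = TRUE, seed = 1L,
                                max_iter = 10L) {
  mode <- match.arg(mode)
  if (is.null(image)) image <- make_phantom(m, 12L, seed = seed)
  assert_square_image(image)
  m <- nrow(image)

  truth <- with_seed(seed + 1L, data.frame(
    true_theta = if (mode != "shift")
      round(stats::runif(n_trials, -180, 180), 1) else numeric(n_trials),
    true_dx = if (mode == "shift")
      round(stats::runif(n_trials, -m / 10, m / 10), 1)
    else if (mode == "both")
      round(stats::runif(n_trials, -m / 20, m / 20), 1)
    else numeric(n_trials),
    true_dy = if (mode == "shift")
      round(stats::runif(n_trials, -m / 10, m / 10), 1)
    else if (mode == "both")
      round(stats::runif(n_trials, -m / 20, m / 20), 1)
    else numeric(n_trials)))

  res <- truth
  res$est_theta <- res$est_dx <- res$est_dy <- NA_real_
  res$n_iter <- NA_integer_
  for (i in seq_len(n_trials)) {
    if (mode == "rotation") {
      test <- rotate_image(image, truth$true_theta[i])
      # estimate_rotation returns the correction; the planted rotation is
      # its negative
      res$est_theta[i] <- -estimate_rotation(image, test,
                                             interpolate = interpolate)
      res$n_iter[i] <- 1L
    } else if (mode == "shift") {
      test <- shift_image(image, truth$true_dx[i], truth$true_dy[i])
      d <- -estimate_shift(image, test, interpolate = interpolate)
      res$est_dx[i] <- d[1]
      res$est_dy[i] <- d[2]
      res$n_iter[i] <- 1L
    } else {
      test <- perturb(image, truth$true_theta[i], truth$true_dx[i],
                      truth$true_dy[i])
      al <- align_images(image, test, max_iter = max_iter,
                         interpolate = interpolate)
      res$est_theta[i] <- -al$theta
      res$est_dx[i] <- -al$dx
      res$est_dy[i] <- -al$dy
      res$n_iter[i] <- al$n_iter
    }
  }
  if (mode != "shift")
    res$err_theta <- angular_error(res$est_theta, res$true_theta)
  if (mode != "rotation") {
    res$err_dx <- abs(res$est_dx - res$true_dx)
    res$err_dy <- abs(res$est_dy - res$true_dy)
  }
  structure(res, mode = mode, interpolate = interpolate, m = m,
            seed = seed,
            class = c("alignment_benchmark", "data.frame"))
}

#' @export
print.alignment_benchmark <- function(x, ...) {
  cat(sprintf("Alignment benchmark: mode = %s, %d trials, m = %d, %s\n",
              attr(x, "mode"), nrow(x), attr(x, "m"),
              if (attr(x, "interpolate")) "spline-refined" else "integer grid"))
  print.data.frame(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Frequency table of benchmark errors
#'
#' Summarizes an [alignment_benchmark()] run the way the alignment tables
#' are reported: counts of absolute errors in the bins `[0, 0.5)`,
#' `[0.5, 1]`, `(1, 5]`, `> 5`, the total (summed) absolute error per
#' parameter, and for the joint mode the distribution and mean of the
#' iteration counts.
#'
#' @param object an `"alignment_benchmark"` data frame.
#' @param ... unused.
#' @return a list with elements `bins` (matrix of counts per parameter),
#'   `total_error` (named vector), and for joint runs `iterations`
#'   (table) and `mean_iterations`; returned invisibly after printing.
#' @export
summary.alignment_benchmark <- function(object, ...) {
  mode <- attr(object, "mode")
  cols <- switch(mode,
                 rotation = c(theta = "err_theta"),
                 shift = c(dx = "err_dx", dy = "err_dy"),
                 both = c(theta = "err_theta", dx = "err_dx", dy = "err_dy"))
  bins <- vapply(cols, function(cn) bin_errors(object[[cn]]),
                 numeric(4))
  total <- vapply(cols, function(cn) sum(object[[cn]]), numeric(1))
  out <- list(bins = bins, total_error = total)
  cat(sprintf("Alignment benchmark (%s, %d trials, %s)\n", mode,
              nrow(object),
              if (attr(object, "interpolate")) "spline-refined"
              else "integer grid"))
  cat("absolute-error frequency:\n")
  print(bins)
  cat("total absolute error:\n")
  print(round(total, 2))
  if (mode == "both") {
    out$iterations <- table(iterations = object$n_iter)
    out$mean_iterations <- mean(object$n_iter)
    cat("iteration counts:\n")
    print(out$iterations)
    cat(sprintf("mean iterations: %.2f\n", out$mean_iterations))
  }
  invisible(out)
}
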
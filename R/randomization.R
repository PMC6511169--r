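#' Monte Carlo p-value from exceedance counts
#'
#' The bias-corrected randomization p-value `(n_exceed + 1) / (n_resamples
#' + 1)`: the smallest attainable value is `1/(n_resamples + 1)`, never 0.
#'
#' @param n_exceed number of null resamples whose statistic was at least as
#'   large as the observed one.
#' @param n_resamples number of null resamples drawn.
#' @return The p-value.
#' @examples
#' p_from_counts(0, 10000) # 1/10001
#' p_from_counts(499, 9999) # 0.05
#' @export
p_from_counts <- function(n_exceed, n_resamples) {
  if (n_resamples < 1) stop("n_resamples must be at least 1")
  if (n_exceed < 0 || n_exceed > n_resamples) {
    stop("n_exceed must lie in 0..n_resamples")
  }
  (n_exceed + 1) / (n_resamples + 1)
}

#' Jitter angles with von Mises noise
#'
#' Adds an independent von Mises(0, kappa) perturbation to every angle and
#' wraps the results back into `[0, 2*pi)`. With large kappa the
#' perturbations are approximately normal with circular standard deviation
#' `1/sqrt(kappa)` (about 1.8 degrees at the default kappa = 1000). This is
#' the tie-breaking device of the rounded-data randomization test.
#'
#' @param sample an [angle_sample], or a numeric vector of radians.
#' @param kappa concentration of the perturbation distribution (positive;
#'   larger means smaller perturbations).
#' @param seed optional integer seed.
#' @return A perturbed, re-sorted [angle_sample].
#' @export
perturb <- function(sample, kappa = 1000, seed = NULL) {
  if (kappa <= 0) stop("kappa must be positive")
  x <- as_angle_sample(sample)
  with_seed(seed, {
    eps <- cpp_rvonmises(length(x), 0, kappa)
    angle_sample(wrap_radians(as.numeric(x) + eps))
  })
}

#' Round angles to a grid of equal divisions
#'
#' Replaces every angle by the nearest multiple of `2*pi/n_bins` (halves
#' round away from zero), wrapping a value that rounds to `2*pi` back to 0,
#' so the output support is `{0, 2*pi/n_bins, ..., 2*pi*(n_bins-1)/n_bins}`.
#' Rounding to the nearest degree is `n_bins = 360`; to the nearest 10
#' degrees, `n_bins = 36`.
#'
#' @param sample an [angle_sample], or a numeric vector of radians.
#' @param n_bins number of equal divisions of the circle (at least 2).
#' @return A rounded [angle_sample].
#' @examples
#' round_to_bins(angle_sample(c(123.4, 355.1), unit = "degrees"), 36)
#' @export
round_to_bins <- function(sample, n_bins) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  x <- as_angle_sample(sample)
  width <- 2 * pi / n_bins
  angle_sample(wrap_radians(floor(as.numeric(x) / width + 0.5) * width))
}

# TRUE when every angle sits on the n_bins grid (within tolerance).
on_grid <- function(x, n_bins, tol = 1e-8) {
  width <- 2 * pi / n_bins
  d <- as.numeric(x) / width
  all(abs(d - round(d)) < tol)
}

#' Monte Carlo Rao spacing test for continuous data
#'
#' Computes U on the observed sample and compares it against U values from
#' `n_resamples` samples of the same size drawn from the circular uniform
#' distribution. The p-value is `(n_exceed + 1)/(n_resamples + 1)`, where
#' ties (a null U equal to the observed U) count as exceedances.
#'
#' @param sample an [angle_sample], or a numeric vector of radians.
#' @param n_resamples number of null resamples (default 10000).
#' @param alpha significance level recorded in the result (default 0.05).
#' @param seed optional integer seed; fixed seed gives a bit-identical
#'   result.
#' @return A `rao_test` object.
#' @examples
#' rao_test_continuous(runif_circular(30, seed = 2), n_resamples = 500,
#'   seed = 1
#' )
#' @export
rao_test_continuous <- function(sample, n_resamples = 10000, alpha = 0.05,
                                seed = NULL) {
  if (n_resamples < 1) stop("n_resamples must be at least 1")
  x <- as_angle_sample(sample)
  n <- length(x)
  u_obs <- rao_u(x)
  n_exceed <- with_seed(seed, {
    sum(cpp_null_u(n, as.integer(n_resamples), 0L, 0, FALSE) >= u_obs)
  })
  p <- p_from_counts(n_exceed, n_resamples)
  new_rao_test(
    method = "continuous", u_rad = u_obs, u_deg = u_obs * 180 / pi,
    n = n, alpha = alpha, p_value = p, reject = p <= alpha,
    n_exceed = n_exceed, n_resamples = as.integer(n_resamples), seed = seed
  )
}

#' Randomization Rao spacing test for rounded (grouped) data
#'
#' The rounded-data variant of the Monte Carlo test. The observed sample --
#' assumed to lie on a grid of `n_bins` equal divisions of the circle -- is
#' first jittered once with von Mises(0, kappa) perturbations, giving the
#' observed statistic. Each null resample is drawn from the continuous
#' uniform distribution, rounded to the same grid, jittered with fresh
#' perturbations, and scored; the p-value is `(n_exceed + 1)/(n_resamples +
#' 1)` with ties counting as exceedances.
#'
#' Choose `kappa` large enough that perturbations are much smaller than the
#' bin width; a warning is issued when the perturbation circular standard
#' deviation `1/sqrt(kappa)` exceeds 10 percent of the bin width.
#'
#' @param sample an [angle_sample] on the `n_bins` grid. A sample off the
#'   grid is rounded with a warning, or rejected when `strict = TRUE`.
#' @param n_bins number of equal angular divisions the data is grouped into
#'   (360 for nearest-degree data, 36 for nearest-10-degrees).
#' @param n_resamples number of null resamples (default 10000).
#' @param kappa perturbation concentration (default 1000).
#' @param alpha significance level recorded in the result (default 0.05).
#' @param seed optional integer seed; fixed seed gives a bit-identical
#'   result.
#' @param strict error (instead of warn-and-round) when the sample is off
#'   the declared grid.
#' @return A `rao_test` object.
#' @examples
#' x <- round_to_bins(runif_circular(50, seed = 3), 36)
#' rao_test_discrete(x, n_bins = 36, n_resamples = 500, seed = 1)
#' @export
rao_test_discrete <- function(sample, n_bins, n_resamples = 10000,
                              kappa = 1000, alpha = 0.05, seed = NULL,
                              strict = FALSE) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  if (n_resamples < 1) stop("n_resamples must be at least 1")
  if (kappa <= 0) stop("kappa must be positive")
  x <- as_angle_sample(sample)
  if (!on_grid(x, n_bins)) {
    if (strict) {
      stop(sprintf(
        "sample values do not lie on the declared grid of %d bins", n_bins
      ))
    }
    warning(sprintf(
      "sample values not on the declared grid of %d bins; rounding", n_bins
    ))
    x <- round_to_bins(x, n_bins)
  }
  width <- 2 * pi / n_bins
  if (1 / sqrt(kappa) > 0.10 * width) {
    warning(sprintf(
      paste0(
        "perturbation SD 1/sqrt(kappa) = %.4f rad exceeds 10%% of the bin ",
        "width %.4f rad; increase kappa so perturbations stay well below ",
        "the rounding granularity"
      ),
      1 / sqrt(kappa), width
    ))
  }
  n <- length(x)
  res <- with_seed(seed, {
    x_pert <- perturb(x, kappa = kappa)
    u_obs <- rao_u(x_pert)
    nulls <- cpp_null_u(n, as.integer(n_resamples), as.integer(n_bins),
                        kappa, TRUE)
    list(u_obs = u_obs, n_exceed = sum(nulls >= u_obs))
  })
  p <- p_from_counts(res$n_exceed, n_resamples)
  new_rao_test(
    method = "discrete", u_rad = res$u_obs,
    u_deg = res$u_obs * 180 / pi, n = n, alpha = alpha,
    p_value = p, reject = p <= alpha, n_exceed = res$n_exceed,
    n_resamples = as.integer(n_resamples), kappa = kappa,
    n_bins = as.integer(n_bins), seed = seed
  )
}
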
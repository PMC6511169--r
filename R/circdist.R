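# Run code under a temporary seed, restoring the caller's RNG state.
# seed = NULL runs on the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Circular uniform sampler
#'
#' Draws n angles i.i.d. uniform on `[0, 2*pi)`.
#'
#' @param n sample size (at least 2).
#' @param seed optional integer seed; when given, the caller's RNG state is
#'   left untouched and repeated calls reproduce the same sample.
#' @return An [angle_sample].
#' @examples
#' runif_circular(10, seed = 1)
#' @export
runif_circular <- function(n, seed = NULL) {
  if (n < 2) stop("sample size must be at least 2")
  with_seed(seed, angle_sample(stats::runif(n, 0, 2 * pi)))
}

#' von Mises sampler
#'
#' Draws from the von Mises distribution with mean direction `mu` and
#' concentration `kappa`, by the Best-Fisher rejection method. `kappa = 0`
#' reduces to the circular uniform; for large `kappa` the distribution
#' approaches a normal with circular standard deviation `1/sqrt(kappa)`.
#'
#' @param n sample size (at least 2).
#' @param mu mean direction in radians.
#' @param kappa concentration parameter, nonnegative.
#' @param seed optional integer seed.
#' @return An [angle_sample].
#' @examples
#' rvonmises(20, mu = pi, kappa = 2, seed = 1)
#' @export
rvonmises <- function(n, mu = 0, kappa = 1, seed = NULL) {
  if (n < 2) stop("sample size must be at least 2")
  if (kappa < 0) stop("kappa must be nonnegative")
  with_seed(seed, angle_sample(cpp_rvonmises(n, wrap_radians(mu), kappa)))
}

#' Skew-normal draws (linear scale)
#'
#' Draws from the skew-normal distribution with location `epsilon`, scale
#' `omega` and shape `alpha`, using the two-normal representation: with
#' `delta = alpha / sqrt(1 + alpha^2)` and independent standard normals
#' `Z0, Z1`, a draw is `epsilon + omega * (delta * |Z0| +
#' sqrt(1 - delta^2) * Z1)`. `alpha = 0` reduces to the normal
#' `N(epsilon, omega^2)`.
#'
#' @param n number of draws.
#' @param epsilon location.
#' @param omega scale (positive).
#' @param alpha shape (skewness) parameter.
#' @param seed optional integer seed.
#' @return Numeric vector of unwrapped (linear) draws.
#' @export
rskewnormal <- function(n, epsilon = 0, omega = 1, alpha = 0, seed = NULL) {
  if (omega <= 0) stop("omega must be positive")
  with_seed(seed, {
    delta <- alpha / sqrt(1 + alpha^2)
    z0 <- abs(stats::rnorm(n))
    z1 <- stats::rnorm(n)
    epsilon + omega * (delta * z0 + sqrt(1 - delta^2) * z1)
  })
}

#' Wrapped skew-normal sampler
#'
#' Linear skew-normal draws (see [rskewnormal()]) wrapped onto the circle
#' modulo `2*pi`. With a scale of the order of radians the wrap matters and
#' is applied explicitly; all parameters are interpreted in radians.
#'
#' @inheritParams rskewnormal
#' @param n sample size (at least 2).
#' @return An [angle_sample].
#' @examples
#' rskewnormal_wrapped(20, epsilon = pi, omega = 2, alpha = 30, seed = 1)
#' @export
rskewnormal_wrapped <- function(n, epsilon = 0, omega = 1, alpha = 0,
                                seed = NULL) {
  if (n < 2) stop("sample size must be at least 2")
  angle_sample(wrap_radians(rskewnormal(n, epsilon, omega, alpha, seed)))
}
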
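# Cache for the parsed critical-value table.
.raospace_env <- new.env(parent = emptyenv())

#' Russell & Levitin critical-value table
#'
#' The published table of critical values (in degrees) for Rao's spacing
#' statistic U, covering every sample size from 4 to 30 and a selection of
#' larger sizes up to 1000, at significance levels 0.001, 0.01, 0.05 and
#' 0.10. The table ships with the package as a plain CSV
#' (`system.file("extdata", "rao_critical_values.csv", package = "raospace")`).
#'
#' @return A data frame with column `n` and one column of critical values
#'   per significance level.
#' @export
rao_critical_table <- function() {
  if (is.null(.raospace_env$table)) {
    path <- system.file("extdata", "rao_critical_values.csv",
                        package = "raospace")
    tab <- utils::read.csv(path, comment.char = "#")
    stopifnot(identical(names(tab)[1], "n"), nrow(tab) == 43L)
    .raospace_env$table <- tab
  }
  .raospace_env$table
}

# Significance levels of the embedded table, as numbers.
rao_table_alphas <- function() {
  as.numeric(sub("alpha_", "", names(rao_critical_table())[-1]))
}

#' Critical value of Rao's spacing statistic
#'
#' Looks up the tabulated critical value of U (in degrees) for a given
#' sample size and significance level. For sample sizes above 30 that fall
#' between tabulated rows the critical value is interpolated linearly in n.
#'
#' @param n sample size, between 4 and 1000.
#' @param alpha significance level; one of 0.001, 0.01, 0.05, 0.10.
#' @return Critical value of U in degrees.
#' @examples
#' critical_value(50, 0.05)
#' critical_value(60, 0.05) # interpolated between n = 50 and n = 75
#' @export
critical_value <- function(n, alpha = 0.05) {
  tab <- rao_critical_table()
  alphas <- rao_table_alphas()
  k <- which(abs(alphas - alpha) < 1e-12)
  if (length(k) != 1L) {
    stop(sprintf(
      "unsupported significance level %g; supported levels: %s",
      alpha, paste(format(alphas), collapse = ", ")
    ))
  }
  if (n < 4) stop("sample size below table support: n must be at least 4")
  if (n > 1000) stop("sample size above table support: n must be at most 1000")
  stats::approx(tab$n, tab[[k + 1L]], xout = n, method = "linear")$y
}

#' Traditional Rao spacing test (critical-value lookup)
#'
#' The classical form of the test: compute U and compare it against the
#' Russell & Levitin critical values. Because only a grid of significance
#' levels is tabulated, the p-value is reported as a bracket (lower, upper)
#' rather than a point value. Reject uniformity at level `alpha` when U
#' exceeds the critical value for that level.
#'
#' This form of the test assumes continuously measured angles. On rounded
#' or grouped data its type I error rate inflates with sample size; use
#' [rao_test_discrete()] there instead.
#'
#' @param sample an [angle_sample], or a numeric vector of radians.
#' @param alpha significance level for the reject decision (a tabulated
#'   level; default 0.05).
#' @return A `rao_test` object with the statistic in both units, the
#'   p-value bracket, and the reject decision.
#' @examples
#' set.seed(1)
#' rao_test_traditional(runif_circular(40))
#' @export
rao_test_traditional <- function(sample, alpha = 0.05) {
  x <- as_angle_sample(sample)
  n <- length(x)
  u_deg <- rao_u(x, units = "degrees")
  alphas <- sort(rao_table_alphas()) # ascending: 0.001 ... 0.10
  crit <- vapply(alphas, function(a) critical_value(n, a), numeric(1))
  # crit decreases as alpha increases, so 'rejected' is monotone:
  # FALSE ... FALSE TRUE ... TRUE along the ascending alpha grid, and the
  # first TRUE gives the tightest bracket containing p.
  rejected <- u_deg > crit
  if (any(rejected)) {
    first <- which(rejected)[1]
    p_bracket <- c(if (first == 1L) 0 else alphas[first - 1L], alphas[first])
  } else {
    p_bracket <- c(alphas[length(alphas)], 1)
  }
  new_rao_test(
    method = "traditional",
    u_rad = u_deg * pi / 180, u_deg = u_deg, n = n,
    p_bracket = p_bracket, alpha = alpha,
    reject = u_deg > critical_value(n, alpha)
  )
}
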
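# Shared constructor for test results. p_bracket is used by the
# traditional test; n_exceed/n_resamples/kappa/n_bins by the simulation
# tests. Unused fields stay NULL and are dropped from serialized output.
new_rao_test <- function(method, u_rad, u_deg, n, alpha,
                         p_value = NULL, p_bracket = NULL, reject = NULL,
                         n_exceed = NULL, n_resamples = NULL,
                         kappa = NULL, n_bins = NULL, seed = NULL) {
  structure(
    list(
      method = method, statistic_rad = u_rad, statistic_deg = u_deg,
      n = n, alpha = alpha, p_value = p_value, p_bracket = p_bracket,
      reject = reject, n_exceed = n_exceed, n_resamples = n_resamples,
      kappa = kappa, n_bins = n_bins, seed = seed
    ),
    class = "rao_test"
  )
}

#' @export
print.rao_test <- function(x, ...) {
  label <- switch(x$method,
    traditional = "Rao's spacing test (critical-value table)",
    continuous = "Rao's spacing test (Monte Carlo, continuous data)",
    discrete = "Rao's spacing test (randomization for rounded data)",
    x$method
  )
  cat("\n\t", label, "\n\n", sep = "")
  cat(sprintf("n = %d, U = %.4f rad (%.2f degrees)\n",
              x$n, x$statistic_rad, x$statistic_deg))
  if (!is.null(x$p_value)) {
    cat(sprintf("p-value = %.6g  [= (%d + 1) / (%d + 1)]\n",
                x$p_value, x$n_exceed, x$n_resamples))
  }
  if (!is.null(x$p_bracket)) {
    cat(sprintf("p-value bracket: %g < p <= %g\n",
                x$p_bracket[1], x$p_bracket[2]))
  }
  if (!is.null(x$reject)) {
    cat(sprintf("reject uniformity at alpha = %g: %s\n",
                x$alpha, if (x$reject) "yes" else "no"))
  }
  if (!is.null(x$n_bins)) {
    cat(sprintf("data grouped into %d bins; perturbation kappa = %g\n",
                x$n_bins, x$kappa))
  }
  if (!is.null(x$seed)) cat(sprintf("seed = %d\n", x$seed))
  cat("\n")
  invisible(x)
}

# Flat named list of the non-NULL fields, used by both serializers.
rao_test_fields <- function(x) {
  out <- x[!vapply(x, is.null, logical(1))]
  if (!is.null(out$p_bracket)) {
    out$p_lower <- out$p_bracket[1]
    out$p_upper <- out$p_bracket[2]
    out$p_bracket <- NULL
  }
  out
}

#' Serialize a test result
#'
#' `rao_test_json()` renders a `rao_test` result as a JSON object (statistic
#' in both units, p-value, resample counts, parameters and seed);
#' `rao_test_csv()` writes the same fields as a one-row CSV.
#'
#' @param x a `rao_test` result.
#' @param path for the CSV form, a file path or `""` for standard output.
#' @return `rao_test_json()` returns a JSON string; `rao_test_csv()` its
#'   one-row data frame, invisibly.
#' @export
rao_test_json <- function(x) {
  stopifnot(inherits(x, "rao_test"))
  jsonlite::toJSON(rao_test_fields(x), auto_unbox = TRUE, digits = NA)
}

#' @rdname rao_test_json
#' @export
rao_test_csv <- function(x, path = "") {
  stopifnot(inherits(x, "rao_test"))
  df <- as.data.frame(rao_test_fields(x))
  utils::write.csv(df, file = path, row.names = FALSE)
  invisible(df)
}
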
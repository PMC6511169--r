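# Default shape parameters for the study distributions: a von Mises with
# mean direction pi and concentration 2, and a wrapped skew-normal with
# location pi, scale 2 rad and shape 30.
default_dist_params <- function(distribution) {
  switch(distribution,
    uniform = list(),
    von_mises = list(mu = pi, kappa = 2),
    skew_normal = list(epsilon = pi, omega = 2, alpha = 30)
  )
}

draw_study_sample <- function(distribution, n, dist_params) {
  switch(distribution,
    uniform = angle_sample(stats::runif(n, 0, 2 * pi)),
    von_mises = angle_sample(
      cpp_rvonmises(n, dist_params$mu, dist_params$kappa)
    ),
    skew_normal = rskewnormal_wrapped(
      n, dist_params$epsilon, dist_params$omega, dist_params$alpha
    )
  )
}

#' Monte Carlo rejection rate of a Rao spacing test variant
#'
#' Draws `replicates` datasets from a configured circular distribution,
#' optionally rounds them to a grid, applies the chosen test variant, and
#' returns the fraction of datasets on which uniformity is rejected. Under
#' uniform data this estimates the type I error rate (rejection counted
#' when p < alpha); under a non-uniform distribution it estimates power
#' (p <= alpha). The traditional variant rejects when U exceeds the
#' critical value at `alpha`.
#'
#' @param test_variant `"traditional"` (critical-value table) or
#'   `"simulation"` (Monte Carlo / randomization p-value).
#' @param distribution `"uniform"`, `"von_mises"` or `"skew_normal"`.
#' @param n sample size per dataset.
#' @param n_bins `NULL` for continuous data, or the number of equal
#'   divisions the data is rounded to before testing.
#' @param replicates number of datasets.
#' @param alpha nominal significance level.
#' @param n_resamples null resamples per simulation test (unused by the
#'   traditional variant).
#' @param kappa perturbation concentration for the rounded-data
#'   randomization test.
#' @param seed optional integer seed for the whole run.
#' @param dist_params named list overriding the distribution defaults
#'   (`mu`, `kappa` for von Mises; `epsilon`, `omega`, `alpha` for the
#'   skew-normal).
#' @return A one-row data frame with the configuration, the rejection rate
#'   and its binomial standard error `sqrt(r * (1 - r) / replicates)`.
#' @examples
#' rejection_rate("traditional", "uniform", n = 50, replicates = 500,
#'   seed = 1
#' )
#' @export
rejection_rate <- function(test_variant = c("traditional", "simulation"),
                           distribution = c("uniform", "von_mises",
                                            "skew_normal"),
                           n, n_bins = NULL, replicates = 2000,
                           alpha = 0.05, n_resamples = 2000, kappa = 1000,
                           seed = NULL, dist_params = NULL) {
  test_variant <- match.arg(test_variant)
  distribution <- match.arg(distribution)
  if (replicates < 1) stop("replicates must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  params <- utils::modifyList(default_dist_params(distribution),
                              as.list(dist_params))
  binning <- if (is.null(n_bins)) "continuous" else as.integer(n_bins)
  if (test_variant == "traditional") {
    crit <- critical_value(n, alpha) # errors for n outside table support
  }

  # Uniform data estimates type I error, counted at p < alpha as a strict
  # inequality; non-uniform data estimates power, counted at p <= alpha.
  # The distinction matters for the simulation tests, whose p-values sit on
  # a grid of round fractions.
  count_reject <- if (distribution == "uniform") {
    function(p) p < alpha
  } else {
    function(p) p <= alpha
  }

  rate <- with_seed(seed, {
    if (test_variant == "traditional" && distribution == "uniform") {
      # Batched fast path: the per-replicate U values under (optionally
      # rounded) uniform sampling, compared against the critical value.
      u_deg <- cpp_null_u(as.integer(n), as.integer(replicates),
                          if (is.null(n_bins)) 0L else as.integer(n_bins),
                          0, FALSE) * 180 / pi
      mean(u_deg > crit)
    } else {
      hits <- 0L
      for (r in seq_len(replicates)) {
        smp <- draw_study_sample(distribution, n, params)
        if (!is.null(n_bins)) smp <- round_to_bins(smp, n_bins)
        hit <- if (test_variant == "traditional") {
          rao_u(smp, units = "degrees") > crit
        } else if (is.null(n_bins)) {
          count_reject(rao_test_continuous(smp, n_resamples)$p_value)
        } else {
          p <- suppressWarnings(
            rao_test_discrete(smp, n_bins, n_resamples, kappa)$p_value
          )
          count_reject(p)
        }
        hits <- hits + hit
      }
      hits / replicates
    }
  })

  data.frame(
    test_variant = test_variant, distribution = distribution, n = n,
    binning = as.character(binning), replicates = replicates,
    alpha = alpha,
    n_resamples = if (test_variant == "simulation") n_resamples else NA,
    kappa = if (test_variant == "simulation" && !is.null(n_bins)) {
      kappa
    } else {
      NA
    },
    rejection_rate = rate,
    binomial_se = sqrt(rate * (1 - rate) / replicates),
    seed = if (is.null(seed)) NA else seed,
    stringsAsFactors = FALSE
  )
}

#' Run a grid of rejection-rate experiments
#'
#' Applies [rejection_rate()] to every configuration in a list, collecting
#' the rows into one tidy data frame. A configuration that errors (for
#' example a traditional test at a sample size outside the critical-value
#' table) is logged as a warning and skipped; the rest of the grid still
#' runs.
#'
#' @param configs nonempty list of named argument lists for
#'   [rejection_rate()].
#' @param out_csv optional path; when given, the result table is also
#'   written there as CSV.
#' @return Data frame with one row per successful configuration.
#' @examples
#' grid <- list(
#'   list(test_variant = "traditional", distribution = "uniform", n = 20,
#'        replicates = 200, seed = 1),
#'   list(test_variant = "traditional", distribution = "uniform", n = 50,
#'        replicates = 200, seed = 2)
#' )
#' run_study_grid(grid)
#' @export
run_study_grid <- function(configs, out_csv = NULL) {
  if (!is.list(configs) || length(configs) == 0L) {
    stop("configs must be a nonempty list of configurations")
  }
  rows <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    rows[[i]] <- tryCatch(
      do.call(rejection_rate, configs[[i]]),
      error = function(e) {
        warning(sprintf("configuration %d skipped: %s", i, conditionMessage(e)),
                call. = FALSE)
        NULL
      }
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("every configuration in the grid failed")
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Quick-look plot of a study result
#'
#' Base-graphics convenience plot of rejection rate against sample size,
#' one line per test variant, with the nominal level marked. Intended as a
#' fast visual check on [run_study_grid()] output, not a publication
#' figure.
#'
#' @param study data frame from [run_study_grid()] (one binning and
#'   distribution at a time plots most readably).
#' @param alpha nominal level to mark with a dashed line.
#' @return The input, invisibly.
#' @export
plot_study <- function(study, alpha = 0.05) {
  variants <- unique(study$test_variant)
  cols <- stats::setNames(seq_along(variants), variants)
  plot(NA,
    xlim = range(study$n), ylim = c(0, max(study$rejection_rate, 0.1)),
    log = "x", xlab = "sample size n", ylab = "rejection rate"
  )
  for (v in variants) {
    d <- study[study$test_variant == v, ]
    d <- d[order(d$n), ]
    graphics::lines(d$n, d$rejection_rate, type = "b", col = cols[[v]],
                    pch = 16)
  }
  graphics::abline(h = alpha, lty = 2)
  graphics::legend("topleft", legend = variants, col = cols, lty = 1,
                   pch = 16, bty = "n")
  invisible(study)
}
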
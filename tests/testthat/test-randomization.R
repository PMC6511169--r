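test_that("p_from_counts implements the bias-corrected Monte Carlo p", {
  expect_equal(p_from_counts(0, 10000), 1 / 10001)
  expect_equal(p_from_counts(10000, 10000), 1)
  expect_equal(p_from_counts(499, 9999), 0.05)
  expect_error(p_from_counts(-1, 100), "0..n_resamples")
  expect_error(p_from_counts(101, 100), "0..n_resamples")
  expect_error(p_from_counts(0, 0), "at least 1")
})

test_that("perturbation jitters at scale 1/sqrt(kappa) and wraps", {
  # large-kappa circular SD of the von Mises noise
  set.seed(11)
  eps <- as.numeric(rvonmises(100000, mu = 0, kappa = 1000))
  eps[eps > pi] <- eps[eps > pi] - 2 * pi # centre on zero
  expect_equal(sd(eps), 1 / sqrt(1000), tolerance = 0.02)

  # kappa -> Inf: the perturbed sample converges to the original
  s <- runif_circular(50, seed = 12)
  p <- perturb(s, kappa = 1e12, seed = 13)
  expect_equal(as.numeric(p), as.numeric(s), tolerance = 1e-4)

  # a value just below 2*pi perturbed past the boundary wraps into range
  s2 <- angle_sample(c(1, 2 * pi - 1e-9))
  set.seed(14)
  for (i in 1:20) {
    out <- as.numeric(perturb(s2, kappa = 50))
    expect_true(all(out >= 0 & out < 2 * pi))
  }
  expect_error(perturb(s2, kappa = 0), "positive")
})

test_that("round_to_bins maps to the nearest grid point with wrap at 2*pi", {
  deg <- function(x) angle_sample(x, unit = "degrees")
  expect_equal(as.numeric(round_to_bins(deg(c(123.4, 20)), 36)),
               c(20, 120) * pi / 180)
  # top half-bin rounds to 360 and wraps to 0
  expect_equal(as.numeric(round_to_bins(deg(c(355.1, 90)), 36)),
               c(0, 90) * pi / 180)
  # idempotence on grid values
  g <- deg(c(0, 10, 340))
  expect_equal(as.numeric(round_to_bins(g, 36)), as.numeric(g))
  # all outputs lie on the grid
  s <- runif_circular(200, seed = 21)
  r <- as.numeric(round_to_bins(s, 7))
  expect_true(all(abs(r / (2 * pi / 7) - round(r / (2 * pi / 7))) < 1e-12))
  expect_error(round_to_bins(s, 1), "at least 2")
})

test_that("continuous Monte Carlo test honours its boundary cases", {
  # equally spaced sample: U = 0, every null U exceeds it, p = 1
  s <- angle_sample(2 * pi * (0:19) / 20)
  res <- rao_test_continuous(s, n_resamples = 500, seed = 31)
  expect_equal(res$p_value, 1)
  expect_equal(res$n_exceed, 500L)

  # coincident sample: U at its maximum, p at the floor 1/(N_R + 1)
  res <- rao_test_continuous(angle_sample(rep(0.5, 20)),
                             n_resamples = 500, seed = 32)
  expect_equal(res$n_exceed, 0L)
  expect_equal(res$p_value, 1 / 501)

  # p-value bounds hold on arbitrary data
  res <- rao_test_continuous(runif_circular(15, seed = 33),
                             n_resamples = 99, seed = 34)
  expect_gte(res$p_value, 1 / 100)
  expect_lte(res$p_value, 1)
})

test_that("simulation tests are bit-reproducible under a fixed seed", {
  s <- runif_circular(30, seed = 41)
  a <- rao_test_continuous(s, n_resamples = 300, seed = 42)
  b <- rao_test_continuous(s, n_resamples = 300, seed = 42)
  expect_identical(a, b)

  d <- round_to_bins(s, 36)
  a <- rao_test_discrete(d, 36, n_resamples = 300, kappa = 1e4, seed = 43)
  b <- rao_test_discrete(d, 36, n_resamples = 300, kappa = 1e4, seed = 43)
  expect_identical(a, b)
  # and the caller's RNG stream is left untouched
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(rao_test_discrete(d, 36, n_resamples = 50, kappa = 1e4,
                              seed = 44))
  expect_identical(runif(1), before)
})

test_that("off-grid samples are rounded with a warning, or refused", {
  s <- runif_circular(20, seed = 51) # continuous, not on any grid
  expect_warning(
    res <- rao_test_discrete(s, 36, n_resamples = 100, kappa = 1e4,
                             seed = 52),
    "not on the declared grid"
  )
  expect_error(
    rao_test_discrete(s, 36, n_resamples = 100, kappa = 1e4, seed = 52,
                      strict = TRUE),
    "do not lie on the declared grid"
  )
  # the permissive path matches testing the pre-rounded sample
  res2 <- rao_test_discrete(round_to_bins(s, 36), 36, n_resamples = 100,
                            kappa = 1e4, seed = 52)
  expect_identical(res$p_value, res2$p_value)
})

test_that("a too-coarse kappa for the bin width triggers the guidance warning", {
  s <- round_to_bins(runif_circular(30, seed = 61), 360)
  # kappa = 1000 gives perturbation SD ~1.8 degrees against 1-degree bins
  expect_warning(
    rao_test_discrete(s, 360, n_resamples = 50, kappa = 1000, seed = 62),
    "exceeds 10% of the bin width"
  )
  # 10-degree bins with the same kappa stay quiet
  s36 <- round_to_bins(s, 36)
  expect_silent(
    rao_test_discrete(s36, 36, n_resamples = 50, kappa = 10000, seed = 63)
  )
})

test_that("Monte Carlo null exceedance matches exact enumeration", {
  # for small n and few bins the rounded-uniform null can be enumerated
  # exactly; the unperturbed Monte Carlo exceedance frequency must agree
  n <- 4L
  n_bins <- 6L
  nr <- 20000L
  set.seed(71)
  u_null <- raospace:::cpp_null_u(n, nr, n_bins, 0, FALSE)
  for (u0 in c(1.5, 2.5, 3.5, 4.5)) {
    exact <- enumerate_discrete_tail(n, n_bins, u0)
    mc <- mean(u_null >= u0)
    se <- sqrt(exact * (1 - exact) / nr)
    expect_lt(abs(mc - exact), 3 * se + 1e-12)
  }
})

test_that("null p-values are valid: P(p <= alpha) <= alpha + 3 SE", {
  m <- 2000L
  set.seed(81)
  p_cont <- replicate(m, {
    rao_test_continuous(runif_circular(20), n_resamples = 199)$p_value
  })
  m_disc <- 1000L
  p_disc <- replicate(m_disc, {
    s <- round_to_bins(runif_circular(20), 36)
    suppressWarnings(rao_test_discrete(s, 36, n_resamples = 199)$p_value)
  })
  for (a in c(0.01, 0.05, 0.1)) {
    expect_lte(mean(p_cont <= a), a + 3 * sqrt(a * (1 - a) / m))
    expect_lte(mean(p_disc <= a), a + 3 * sqrt(a * (1 - a) / m_disc))
  }
})

test_that("concentrating the sample into fewer bins cannot raise p on average", {
  # n = 24 points spread evenly over k of 36 bins, k decreasing: the mean
  # p-value over replicate seeds must be nonincreasing in concentration
  n <- 24
  width <- 2 * pi / 36
  mean_p <- vapply(c(12, 6, 3, 1), function(k) {
    bins <- rep(seq(0, 36 - 1, by = 36 / k), length.out = n)
    s <- angle_sample(sort(bins) * width)
    mean(vapply(1:30, function(seed) {
      suppressWarnings(
        rao_test_discrete(s, 36, n_resamples = 299, seed = seed)$p_value
      )
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_p) <= 0.02))
})

test_that("results serialize to JSON and one-row CSV and round-trip", {
  res <- suppressWarnings(
    rao_test_discrete(round_to_bins(runif_circular(25, seed = 91), 36),
                      36, n_resamples = 200, seed = 92)
  )
  parsed <- jsonlite::fromJSON(rao_test_json(res))
  expect_equal(parsed$p_value, res$p_value)
  expect_equal(parsed$statistic_rad, res$statistic_rad)
  expect_equal(parsed$n_exceed, res$n_exceed)
  expect_equal(parsed$kappa, 1000)
  expect_equal(parsed$n_bins, 36)

  csv <- withr::local_tempfile(fileext = ".csv")
  df <- rao_test_csv(res, csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), 1L)
  expect_equal(back$p_value, res$p_value)
  expect_equal(back$method, "discrete")
})
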
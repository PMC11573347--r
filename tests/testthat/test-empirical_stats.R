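test_that("empirical SDF counts droplets strictly above each threshold", {
  sdf <- empirical_sdf(make_table(c(1, 2, 2, 5)))
  expect_equal(sdf$thresholds, c(1, 2, 5))
  expect_equal(sdf$survival, c(3 / 4, 1 / 4, 0))
  expect_equal(sdf_eval(sdf, c(0.5, 2, 5, 7)), c(1, 1 / 4, 0, 0))
  expect_true(all(diff(sdf$survival) <= 0))

  sdf2 <- empirical_sdf(make_table(c(1, 3), counts = c(2, 2)))
  expect_equal(sdf_eval(sdf2, 1), 0.5)
})

test_that("empirical SDF converges to the analytic log-normal survival", {
  s0 <- 2; sigma <- 0.7
  withr::local_seed(8)
  tab <- make_table(stats::rlnorm(1e5, log(s0), sigma))
  sdf <- empirical_sdf(tab)
  gap <- max(abs(sdf$survival - lognormal_sdf(sdf$thresholds, s0, sigma)))
  expect_lt(gap, 0.01)
})

test_that("fractional moments honour counts and work in log space", {
  tab <- make_table(c(1, 2, 4), counts = c(2, 1, 1))
  expect_equal(size_moment(tab, 1), 2)
  expect_equal(size_moment(tab, 1e-6), 1, tolerance = 1e-4)
  # wide-ranged sizes: naive powering of 1e-200 underflows the summand to
  # zero, log-space accumulation keeps the k = 1 moment exact; a moment
  # that genuinely exceeds double range is a loud error, not Inf
  wide <- make_table(c(1e-200, 1e200))
  expect_equal(size_moment(wide, 1), 5e199)
  expect_error(size_moment(wide, 2), "overflow")

  # Monte-Carlo check against the analytic moment
  withr::local_seed(12)
  s <- stats::rlnorm(1e5, -1.5, 1)   # s_c = 1, sigma = 1
  se <- stats::sd(s^2) / sqrt(1e5)
  expect_equal(size_moment(make_table(s), 2), exp(-1), tolerance = 3 * se)
})

test_that("moment sets average replicates with standard errors of the mean", {
  s1 <- concentration_series(list(make_table(c(1, 2), conc = 1, rep = 1L),
                                  make_table(c(1, 2), conc = 1, rep = 2L)))
  ms <- moment_sets(s1, 1)[[1L]]
  expect_equal(ms$err, 0)

  # replicates engineered to have <s> = 1, 2, 3
  s2 <- concentration_series(list(make_table(1, conc = 1, rep = 1L),
                                  make_table(2, conc = 1, rep = 2L),
                                  make_table(3, conc = 1, rep = 3L)))
  ms <- moment_sets(s2, 1)[[1L]]
  expect_equal(ms$mean, 2)
  expect_equal(ms$err, stats::sd(1:3) / sqrt(3))
  expect_equal(ms$n_replicates, 3L)

  # analytic input passes through exactly
  spec <- synthetic_model_spec(sigma = 0.8)
  exact <- exact_moment_series(spec, c(0.5, 1))
  expect_identical(moment_sets(exact, c(0.5, 1)), exact)
})

test_that("moment ratios equal s_c e^{sigma^2 (k-1)} on exact log-normal moments", {
  spec <- synthetic_model_spec(sigma = 0.6)
  ms <- exact_moment_series(spec, c(0.5, 1, 1.5, 2, 2.5, 3))
  for (m in ms) {
    s_c <- characteristic_size_model(spec, m$concentration)
    for (k in c(0.5, 1, 1.5, 2)) {
      r <- moment_ratio(m, k)
      expect_equal(r$value, s_c * exp(0.6^2 * (k - 1)), tolerance = 1e-12)
      expect_equal(r$error, 0)
    }
    # k = 1 gives the characteristic size identically in sigma
    expect_equal(moment_ratio(m, 1)$value, s_c, tolerance = 1e-12)
  }
  expect_error(moment_ratio(ms[[1L]], 3), "not available")
})

test_that("moment-ratio errors propagate the two SEMs independently", {
  ms <- new_moment_set(concentration = 1, k = c(1, 2),
                       mean = c(2, 6), err = c(0.2, 0.9), n_replicates = 3L,
                       replicate_moments = matrix(c(2, 6), 1))
  r <- moment_ratio(ms, 1)
  expect_equal(r$value, 3)
  expect_equal(r$error, 3 * sqrt((0.9 / 6)^2 + (0.2 / 2)^2))
})

test_that("log-normal fits recover location and width in both variance modes", {
  tab <- make_table(c(exp(-1), exp(1)))
  pop <- fit_lognormal(tab, "population")
  expect_equal(pop$ln_s0, 0)
  expect_equal(pop$sigma, 1)
  samp <- fit_lognormal(tab, "sample")
  expect_equal(samp$sigma, sqrt(2))   # n-1 denominator at n = 2

  expect_error(fit_lognormal(make_table(c(3, 3, 3))), "degenerate")
  degen <- fit_lognormal(make_table(c(3, 3)), allow_degenerate = TRUE)
  expect_equal(degen$sigma, 0)
  expect_equal(exp(degen$ln_s0), 3)

  withr::local_seed(4)
  big <- make_table(stats::rlnorm(1e5, log(2), 0.7))
  fit <- fit_lognormal(big)
  expect_equal(fit$ln_s0, log(2), tolerance = 3 * 0.7 / sqrt(1e5) / log(2))
  expect_equal(fit$sigma, 0.7, tolerance = 3 / sqrt(2e5))
  # internal consistency of the derived characteristic size
  expect_equal(fit$s_c_derived, exp(fit$ln_s0 + 1.5 * fit$sigma^2))
})

test_that("the log-normal survival function has the erfc form", {
  expect_equal(lognormal_sdf(1, 1, 1), 0.5)
  expect_equal(lognormal_sdf(exp(1), 1, 1), stats::pnorm(1, lower.tail = FALSE))
  expect_equal(lognormal_sdf(1e-12, 1, 1), 1, tolerance = 1e-9)
  expect_equal(lognormal_sdf(1e12, 1, 1), 0, tolerance = 1e-9)
  # agrees with plnorm whatever the parameters
  expect_equal(lognormal_sdf(3.2, 1.4, 0.6),
               stats::plnorm(3.2, log(1.4), 0.6, lower.tail = FALSE))
})

test_that("empirical characteristic size is the second-to-first moment ratio", {
  expect_equal(characteristic_size_empirical(make_table(c(1, 1, 1))), 1)
  expect_equal(characteristic_size_empirical(make_table(c(1, 3))), 2.5)
  withr::local_seed(7)
  spec <- synthetic_model_spec()
  tab <- make_table(sample_droplets(spec, 3.5, 1e5))
  s_c <- characteristic_size_model(spec, 3.5)   # = 10/3
  expect_equal(characteristic_size_empirical(tab), s_c, tolerance = 0.05)
})

test_that("log-moments are convex in k and covariant under size rescaling", {
  withr::local_seed(19)
  for (i in 1:20) {
    tab <- make_table(exp(stats::rnorm(30, 0, 2)),
                      counts = sample(1:4, 30, replace = TRUE))
    k <- seq(0.25, 3, by = 0.25)
    lm_ <- log(size_moment(tab, k))
    expect_true(all(diff(lm_, differences = 2) > -1e-8))   # Lyapunov
    lambda <- exp(stats::runif(1, -2, 2))
    scaled <- make_table(tab$size * lambda, tab$count)
    expect_equal(size_moment(scaled, k), size_moment(tab, k) * lambda^k,
                 tolerance = 1e-9)
    f1 <- fit_lognormal(tab); f2 <- fit_lognormal(scaled)
    expect_equal(f2$ln_s0, f1$ln_s0 + log(lambda), tolerance = 1e-9)
    expect_equal(f2$sigma, f1$sigma, tolerance = 1e-9)
  }
})

test_that("binned and raw representations of a multiset give identical statistics", {
  raw <- make_table(c(1, 1, 2, 2, 2, 7))
  binned <- make_table(c(1, 2, 7), counts = c(2, 3, 1))
  expect_equal(size_moment(raw, c(0.5, 1, 2)), size_moment(binned, c(0.5, 1, 2)))
  expect_equal(empirical_sdf(raw)$survival, empirical_sdf(binned)$survival)
  expect_equal(fit_lognormal(raw)$sigma, fit_lognormal(binned)$sigma)
})

test_that("characteristic sizes agree along the whole consistency chain", {
  # empirical <s^2>/<s>, the log-normal-fit derived s_c, and the
  # generative s_c must coincide on a large exact log-normal sample
  withr::local_seed(23)
  spec <- synthetic_model_spec()
  rho <- 4
  tab <- make_table(sample_droplets(spec, rho, 1e5))
  s_c <- characteristic_size_model(spec, rho)
  expect_equal(characteristic_size_empirical(tab) / s_c, 1, tolerance = 1e-2)
  expect_equal(fit_lognormal(tab)$s_c_derived / s_c, 1, tolerance = 1e-2)
})
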
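test_that("characteristic size follows the divergence law", {
  expect_equal(characteristic_size_model(
    synthetic_model_spec(a = 1, phi = 1, rho_c = 5), 4), 5)
  expect_equal(characteristic_size_model(
    synthetic_model_spec(a = 2, phi = 1, rho_c = 5), 2.5), 4)
  expect_equal(characteristic_size_model(
    synthetic_model_spec(a = 1, phi = 2, rho_c = 10), 9), 100)
  # strictly increasing towards the critical point, divergent there
  spec <- synthetic_model_spec(rho_c = 5)
  rho <- seq(0.5, 4.9, by = 0.1)
  expect_true(all(diff(characteristic_size_model(spec, rho)) > 0))
  expect_error(characteristic_size_model(spec, 5), "subsaturated")
  expect_error(characteristic_size_model(spec, 6), "subsaturated")
})

test_that("sampled droplets follow the log-normal with median s_c e^{-3 sigma^2/2}", {
  # degenerate width: all draws collapse onto s_0 = s_c
  spec0 <- synthetic_model_spec(sigma = 0)
  expect_equal(sample_droplets(spec0, 4, 10), rep(5, 10))

  spec <- synthetic_model_spec(a = 1, phi = 1, sigma = 1, rho_c = 5)
  withr::local_seed(101)
  s <- sample_droplets(spec, 4, 1e5)
  # closed-form log-space mean: ln s0 = ln 5 - 1.5, sd = 1
  expect_equal(mean(log(s)), log(5) - 1.5, tolerance = 3 / sqrt(1e5) / abs(log(5) - 1.5))
  expect_equal(stats::sd(log(s)), 1, tolerance = 0.01)
  # <s^2>/<s> estimates s_c = 5 (moment identity); generous Monte-Carlo band
  expect_equal(mean(s^2) / mean(s), 5, tolerance = 0.05)
})

test_that("generated series have the requested structure and are reproducible", {
  spec <- synthetic_model_spec(concentrations = c(1, 2, 3), n_replicates = 2,
                               n_droplets = 50, seed = 9)
  series <- generate_series(spec)
  expect_length(series$tables, 6L)
  expect_equal(series$rho_c, 5)
  expect_identical(series, generate_series(spec))
  # replicate substreams differ from each other
  expect_false(identical(series$tables[[1L]]$size, series$tables[[2L]]$size))
  # and the global RNG stream is left untouched
  withr::local_seed(1)
  before <- .Random.seed
  invisible(generate_series(spec))
  expect_identical(.Random.seed, before)
})

test_that("binning preserves moments to within bin resolution", {
  raw_spec <- synthetic_model_spec(n_droplets = 5000, n_replicates = 1,
                                   concentrations = c(2, 4), seed = 5)
  bin_spec <- synthetic_model_spec(n_droplets = 5000, n_replicates = 1,
                                   concentrations = c(2, 4), seed = 5,
                                   binning = list(n_bins = 80, spacing = "log"))
  raw <- generate_series(raw_spec)
  binned <- generate_series(bin_spec)
  for (i in seq_along(raw$tables)) {
    expect_equal(n_droplets(binned$tables[[i]]), 5000)
    for (k in c(0.5, 1, 2)) {
      expect_equal(size_moment(binned$tables[[i]], k),
                   size_moment(raw$tables[[i]], k), tolerance = 0.02)
    }
  }
  expect_error(synthetic_model_spec(binning = list(n_bins = 1)), "n_bins")
  expect_error(synthetic_model_spec(count_noise = "poisson"), "binning")
})

test_that("poisson count noise perturbs abundances but keeps the size grid", {
  spec <- synthetic_model_spec(n_droplets = 2000, n_replicates = 1,
                               concentrations = 2, seed = 3,
                               binning = list(n_bins = 40, spacing = "log"),
                               count_noise = "poisson")
  noiseless <- synthetic_model_spec(n_droplets = 2000, n_replicates = 1,
                                    concentrations = 2, seed = 3,
                                    binning = list(n_bins = 40,
                                                   spacing = "log"))
  tab <- generate_series(spec)$tables[[1L]]
  ref <- generate_series(noiseless)$tables[[1L]]
  expect_true(all(tab$size %in% ref$size))
  expect_false(identical(tab$count, ref$count))
})

test_that("analytic moments match numerical integration of the density", {
  # trivial forced-zero exponent and k -> moments identities
  expect_equal(lognormal_moment(1, 1, 3), 1)
  expect_equal(exact_moment_series(synthetic_model_spec(sigma = 1),
                                   3)[[1L]]$mean, 1 * characteristic_size_model(
                                     synthetic_model_spec(sigma = 1), 0.5)^3)
  # numerical-integration oracle in log space
  num_moment <- function(s_c, sigma, k) {
    mu <- log(s_c) - 1.5 * sigma^2
    # the integrand is a Gaussian in log space centred at mu + k sigma^2
    ctr <- mu + k * sigma^2
    stats::integrate(function(y) exp(k * y) * stats::dnorm(y, mu, sigma),
                     ctr - 13 * sigma, ctr + 13 * sigma,
                     rel.tol = 1e-10)$value
  }
  expect_equal(lognormal_moment(1, 1, 1), num_moment(1, 1, 1),
               tolerance = 1e-9)
  expect_equal(lognormal_moment(1, 1, 1), exp(-1), tolerance = 1e-12)
  expect_equal(lognormal_moment(2, 0.5, 2), num_moment(2, 0.5, 2),
               tolerance = 1e-9)
  expect_equal(lognormal_moment(2, 0.5, 2), 4 * exp(-0.25),
               tolerance = 1e-12)
  expect_equal(lognormal_moment(1, 1, 0.5), exp(-0.625), tolerance = 1e-12)
})

test_that("exact moment series satisfy the characteristic-size identity and scale covariance", {
  for (sigma in c(0.3, 1, 1.7)) {
    spec <- synthetic_model_spec(sigma = sigma)
    ms <- exact_moment_series(spec, c(1, 2))
    for (m in ms) {
      expect_equal(m$mean[m$k == 2] / m$mean[m$k == 1],
                   characteristic_size_model(spec, m$concentration),
                   tolerance = 1e-12)
    }
  }
  # multiplying a by lambda multiplies <s^k> by lambda^k
  lambda <- 3.7
  k <- c(0.5, 1, 2.25)
  base <- exact_moment_series(synthetic_model_spec(a = 1), k)
  scaled <- exact_moment_series(synthetic_model_spec(a = lambda), k)
  for (i in seq_along(base)) {
    expect_equal(scaled[[i]]$mean, base[[i]]$mean * lambda^k,
                 tolerance = 1e-12)
  }
})

test_that("the generator's fitted log-width is flat in concentration", {
  series <- generate_series(synthetic_model_spec(seed = 21))
  flat <- sigma_flatness(series)
  expect_lt(abs(flat$t), 3)
  expect_equal(flat$fits$sigma, rep(1, 5), tolerance = 0.05)
})
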
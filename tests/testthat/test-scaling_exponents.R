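test_that("weighted linear fits solve the weighted normal equations", {
  fit <- weighted_linear_fit(c(1, 2), c(1, 2), c(1, 1))
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)

  # a wildly uncertain third point barely moves the fit
  fit <- weighted_linear_fit(c(0, 1, 2), c(0, 1, 9), c(1, 1, 1e6))
  expect_equal(fit$slope, 1, tolerance = 1e-4)
  expect_equal(fit$intercept, 0, tolerance = 1e-4)

  expect_error(weighted_linear_fit(c(2, 2, 2), c(1, 2, 3), c(1, 1, 1)),
               "singular")

  # random heteroscedastic fixtures against the matrix-algebra oracle
  withr::local_seed(33)
  for (i in 1:1000) {
    n <- sample(3:12, 1)
    x <- stats::rnorm(n); x[1] <- x[1] + 3   # guard against degenerate spread
    y <- stats::rnorm(n)
    err <- stats::runif(n, 0.1, 10)
    fit <- weighted_linear_fit(x, y, err)
    oracle <- wls_oracle(x, y, 1 / err^2)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
    # known-variance parameter errors are the Fisher-information ones
    expect_equal(fit$slope_err, sqrt(oracle$cov[2, 2]), tolerance = 1e-8)
    expect_equal(fit$intercept_err, sqrt(oracle$cov[1, 1]), tolerance = 1e-8)
    expect_equal(fit$cov_ab, oracle$cov[1, 2], tolerance = 1e-8)
  }
})

test_that("weighted fits agree with lm point estimates and flag uniform weights", {
  withr::local_seed(14)
  x <- 1:6; y <- stats::rnorm(6, x); err <- stats::runif(6, 0.5, 2)
  fit <- weighted_linear_fit(x, y, err)
  lmfit <- stats::lm(y ~ x, weights = 1 / err^2)
  expect_equal(fit$slope, unname(stats::coef(lmfit)[2]), tolerance = 1e-12)
  expect_equal(fit$intercept, unname(stats::coef(lmfit)[1]), tolerance = 1e-12)

  unif <- weighted_linear_fit(x, y)
  expect_true(unif$uniform_weights)
  ols <- stats::lm(y ~ x)
  expect_equal(unif$slope_err,
               unname(sqrt(diag(stats::vcov(ols)))[2]), tolerance = 1e-10)
})

test_that("the dimensionless distance from criticality is (rho_c - rho)/rho_c", {
  expect_equal(log_distance(4, 5), 0.2)
  expect_equal(log_distance(2.5, 5), 0.5)
  expect_lt(log_distance(5 - 1e-9, 5), 1e-9)
  expect_error(log_distance(5, 5), "below the critical")
  expect_error(log_distance(-1, 5), "below the critical")
})

test_that("phi is recovered exactly from noise-free moments for any generative phi", {
  for (phi_true in c(1, 2)) {
    spec <- synthetic_model_spec(phi = phi_true, sigma = 0.8, rho_c = 5,
                                 concentrations = 1:4)
    ms <- exact_moment_series(spec, seq(0.5, 3, by = 0.5))
    fit <- estimate_phi(ms, rho_c = 5, k_grid = c(0.5, 1, 1.5, 2))
    slopes <- vapply(fit$per_k, `[[`, numeric(1), "slope")
    expect_equal(unname(slopes), rep(phi_true, 4), tolerance = 1e-10)
    expect_equal(fit$phi, phi_true, tolerance = 1e-10)
  }
})

test_that("pooling across k reduces to the arithmetic mean under equal errors", {
  phi_k <- c(0.9, 1.0, 1.1, 1.4)
  pooled <- dropletscaling:::pool_weighted(phi_k, rep(0.05, 4))
  expect_equal(pooled$mean, mean(phi_k))
  expect_equal(pooled$err, 0.05 / 2)
  # inverse-variance weighting favours the precise estimate
  pooled <- dropletscaling:::pool_weighted(c(1, 2), c(0.01, 100))
  expect_equal(pooled$mean, 1, tolerance = 1e-4)
})

test_that("the mean-size slope gives alpha = 1 - m/phi", {
  spec <- synthetic_model_spec(phi = 1, sigma = 0.8, concentrations = 1:4)
  ms <- exact_moment_series(spec, 1)
  fit <- estimate_m_alpha(ms, rho_c = 5, phi_used = 1)
  expect_equal(fit$m, 1, tolerance = 1e-10)
  expect_equal(fit$alpha, 0, tolerance = 1e-10)

  # arithmetic of the exponent relation
  expect_equal(1 - 0.99 / 1, 0.01)
  fit2 <- estimate_m_alpha(ms, rho_c = 5, phi_used = 2)
  expect_equal(fit2$alpha, 1 - fit2$m / 2)
})

test_that("k-grid selection ranks candidates by regression linearity", {
  spec <- synthetic_model_spec(sigma = 0.8, concentrations = 1:4)
  ms <- exact_moment_series(spec, seq(0.25, 4, by = 0.25))
  cand <- seq(0.25, 3, by = 0.25)
  # all candidates are exactly linear: documented ascending-k tie-break
  expect_equal(select_k_grid(ms, 5, cand, n_select = 4),
               c(0.25, 0.5, 0.75, 1))
  expect_equal(select_k_grid(ms, 5, cand, n_select = length(cand)), cand)

  # corrupt the moments above k = 2 only; every ratio touching them
  # (candidates k > 1) loses linearity, so the four clean low-k
  # candidates must win
  noisy <- lapply(ms, function(m) {
    bump <- 1 + 0.3 * (m$k > 2) * sin(7 * m$concentration + m$k)
    m$mean <- m$mean * bump
    m
  })
  sel <- select_k_grid(noisy, 5, cand, n_select = 4)
  expect_true(all(sel <= 1))
})

test_that("exponent estimates are invariant under global size rescaling", {
  series <- generate_series(synthetic_model_spec(n_droplets = 400, seed = 6))
  scaled <- series
  scaled$tables <- lapply(series$tables, function(t)
    droplet_table(t$size * 137.5, t$count, concentration = t$concentration,
                  replicate = t$replicate))
  f1 <- estimate_phi(series, 5); f2 <- estimate_phi(scaled, 5)
  expect_equal(f2$phi, f1$phi, tolerance = 1e-9)
  a1 <- estimate_m_alpha(series, 5); a2 <- estimate_m_alpha(scaled, 5)
  expect_equal(a2$m, a1$m, tolerance = 1e-9)
  expect_equal(a2$alpha, a1$alpha, tolerance = 1e-9)
})

test_that("noise-free slopes are exact on any subset of concentrations", {
  spec <- synthetic_model_spec(sigma = 0.8, concentrations = 1:4)
  ms <- exact_moment_series(spec, c(0.5, 1, 1.5, 2, 2.5, 3))
  full <- estimate_phi(ms, 5, c(0.5, 1, 1.5, 2))
  # dropping the concentration farthest from rho_c changes nothing
  trimmed <- estimate_phi(ms, 5, c(0.5, 1, 1.5, 2), exclusions = 1)
  expect_equal(trimmed$phi, full$phi, tolerance = 1e-10)
  expect_equal(vapply(trimmed$per_k, `[[`, numeric(1), "n_points"),
               vapply(full$per_k, `[[`, numeric(1), "n_points") - 1L,
               ignore_attr = TRUE)
})

test_that("estimator preconditions are enforced", {
  spec <- synthetic_model_spec(concentrations = 1:4)
  ms <- exact_moment_series(spec, c(1, 2))
  expect_error(estimate_phi(ms, rho_c = 3), "exceed every")
  expect_error(estimate_phi(ms, 5, k_grid = numeric()), "empty")
  expect_error(estimate_phi(ms, 5, k_grid = 1, exclusions = 1:3),
               "insufficient data")
})
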
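# Shared fixtures: built in code, no data files.

make_table <- function(sizes, counts = 1, conc = 1, rep = 1L) {
  droplet_table(sizes, counts, concentration = conc, replicate = rep)
}

# A small two-concentration series with exactly known sizes.
tiny_series <- function() {
  concentration_series(list(
    make_table(c(1, 2, 4), conc = 1, rep = 1L),
    make_table(c(2, 3, 5), conc = 1, rep = 2L),
    make_table(c(2, 4, 8), conc = 2, rep = 1L),
    make_table(c(4, 6, 10), conc = 2, rep = 2L)))
}

# Random raw/binned fixture for roundtrip properties: sizes log-uniform
# over [1e-3, 1e3].
random_series <- function(n_conc = 3, n_rep = 2, n = 20) {
  tables <- list()
  for (ci in seq_len(n_conc)) for (ri in seq_len(n_rep)) {
    tables[[length(tables) + 1L]] <- droplet_table(
      exp(stats::runif(n, log(1e-3), log(1e3))),
      count = sample(1:5, n, replace = TRUE),
      concentration = ci, replicate = ri)
  }
  concentration_series(tables)
}

# Brute-force weighted normal equations via matrix algebra, independent of
# weighted_linear_fit's accumulation.
wls_oracle <- function(x, y, w) {
  X <- cbind(1, x)
  xtwx <- t(X) %*% (w * X)
  beta <- solve(xtwx, t(X) %*% (w * y))
  list(intercept = beta[1L], slope = beta[2L], cov = solve(xtwx))
}

# The 100-seed parameter-recovery study at the generator defaults, with
# rho_c re-estimated per series; cached so several test files can assert
# on different aspects of the same study.
recovery_study <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    res <- t(sapply(1:100, function(sd) {
      series <- generate_series(synthetic_model_spec(seed = sd))
      cp <- rhoc_moment_intercept(series)
      ef <- estimate_phi(series, cp$rho_c)
      ma <- estimate_m_alpha(series, cp$rho_c, phi_used = ef$phi)
      c(phi = ef$phi, phi_err = ef$phi_err, m = ma$m, alpha = ma$alpha,
        rho_c = cp$rho_c)
    }))
    cache <<- as.data.frame(res)
    cache
  }
})
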
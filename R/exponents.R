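#' Dimensionless distance from the critical concentration
#'
#' \eqn{|\tilde\rho| = (\rho_c - \rho)/\rho_c} for concentrations in the
#' subsaturated regime \eqn{0 < \rho < \rho_c}. This dimensionless variable
#' is what makes droplet data from different experiments comparable.
#'
#' @param rho concentration(s) (uM).
#' @param rho_c critical concentration (uM).
#' @return `|rho_tilde|` in (0, 1).
#' @export
log_distance <- function(rho, rho_c) {
  if (any(rho <= 0) || any(rho >= rho_c))
    stop("rho must lie in (0, rho_c): the scaling analysis is defined only ",
         "below the critical concentration", call. = FALSE)
  (rho_c - rho) / rho_c
}

#' Estimate the divergence exponent phi from moment ratios
#'
#' For each moment order k, the ratio
#' \eqn{\langle s^{k+1}\rangle/\langle s^k\rangle} is proportional to the
#' characteristic size and hence to \eqn{|\tilde\rho|^{-\phi}}; regressing
#' its logarithm on \eqn{\ln(1/|\tilde\rho|)} with inverse-variance weights
#' gives a slope \eqn{\phi_k \pm \sigma_k} per k. The pooled estimate is
#' the inverse-variance weighted average
#' \eqn{\bar\phi = \sum_k \phi_k/\sigma_k^2 \,/\, \sum_k 1/\sigma_k^2}
#' with \eqn{\mathrm{Var}(\bar\phi) = 1/\sum_k 1/\sigma_k^2}. Replicate
#' standard errors are moved to the log scale by the first-order delta
#' method, err(ln y) = err(y)/y.
#'
#' @param series a [concentration_series], or a list of precomputed
#'   `moment_set` objects (e.g. from [exact_moment_series()]).
#' @param rho_c critical concentration used for the distances; must exceed
#'   every analysed concentration.
#' @param k_grid moment orders (the ratios also require `k + 1`, computed
#'   internally).
#' @param exclusions concentrations dropped from the fit (`NULL` defers to
#'   the series' own exclusion set). Typical use: drop the lowest measured
#'   concentration, which lies furthest from the scaling regime.
#' @return An object of class `exponent_fit` with `per_k` (one [wls_fit]
#'   per k), `phi`, `phi_err`, `k_grid`, `rho_c_used`, `exclusions`.
#' @export
estimate_phi <- function(series, rho_c, k_grid = k_grid_preset("fus"),
                         exclusions = NULL) {
  k_grid <- sort(as.numeric(k_grid))
  if (length(k_grid) == 0L) stop("k_grid is empty", call. = FALSE)
  ms <- moments_for_fit(series, rho_c, unique(c(k_grid, k_grid + 1)),
                        exclusions)
  per_k <- lapply(k_grid, function(k) {
    rat <- lapply(ms, moment_ratio, k = k)
    y <- vapply(rat, `[[`, numeric(1), "value")
    yerr <- vapply(rat, `[[`, numeric(1), "error")
    x <- log(1 / vapply(ms, function(m) log_distance(m$concentration, rho_c),
                        numeric(1)))
    weighted_linear_fit(x, log(y), log_err(y, yerr))
  })
  names(per_k) <- as.character(k_grid)
  pooled <- pool_weighted(vapply(per_k, `[[`, numeric(1), "slope"),
                          vapply(per_k, `[[`, numeric(1), "slope_err"))
  structure(list(per_k = per_k, phi = pooled$mean, phi_err = pooled$err,
                 m = NULL, m_err = NULL, alpha = NULL, phi_used = NULL,
                 k_grid = k_grid, rho_c_used = rho_c,
                 exclusions = exclusions %||% series$excluded %||% numeric()),
            class = "exponent_fit")
}

# Common validation + moment computation for the regression estimators.
moments_for_fit <- function(series, rho_c, k_need, exclusions) {
  if (is_moment_set_list(series)) {
    ms <- series
    if (!is.null(exclusions) && length(exclusions))
      ms <- Filter(function(m) !(m$concentration %in% exclusions), ms)
  } else {
    stopifnot(inherits(series, "concentration_series"))
    ms <- moment_sets(apply_exclusions(series, exclusions), k_need)
  }
  conc <- vapply(ms, `[[`, numeric(1), "concentration")
  if (length(conc) < 2L)
    stop("insufficient data: need >= 2 non-excluded concentrations",
         call. = FALSE)
  if (any(conc >= rho_c))
    stop("rho_c must exceed every analysed concentration", call. = FALSE)
  ms
}

# err(ln y) = err(y)/y to first order; exactly 0 stays 0.
log_err <- function(y, yerr) yerr / y

# Inverse-variance weighted mean; equal weights when any error is zero
# (the noise-free case, where all estimates coincide anyway).
pool_weighted <- function(values, errs) {
  if (any(errs <= 0) || any(!is.finite(errs))) {
    return(list(mean = mean(values),
                err = if (length(values) > 1L) stats::sd(values) else 0))
  }
  w <- 1 / errs^2
  list(mean = sum(w * values) / sum(w), err = sqrt(1 / sum(w)))
}

#' Estimate the prefactor exponent alpha from the mean droplet size
#'
#' The slope m of the error-weighted regression of
#' \eqn{\ln\langle s\rangle} on \eqn{\ln(1/|\tilde\rho|)} equals
#' \eqn{\phi(1-\alpha)}, so \eqn{\alpha = 1 - m/\phi_{\rm used}}. With the
#' conventional \eqn{\phi_{\rm used} = 1} this reduces to
#' \eqn{\alpha = 1 - m}; an exactly log-normal size distribution forces
#' \eqn{\alpha = 0}.
#'
#' @inheritParams estimate_phi
#' @param phi_used the value of phi inserted in the exponent relation
#'   (default 1, or pass the pooled estimate from [estimate_phi()]).
#' @return An `exponent_fit` carrying `m`, `m_err`, `alpha`, `phi_used`,
#'   and the mean-size regression as `per_k[["mean_size"]]`.
#' @export
estimate_m_alpha <- function(series, rho_c, phi_used = 1, exclusions = NULL) {
  stopifnot(phi_used > 0)
  ms <- moments_for_fit(series, rho_c, 1, exclusions)
  y <- vapply(ms, function(m) moment_at(m, 1)$mean, numeric(1))
  yerr <- vapply(ms, function(m) moment_at(m, 1)$err, numeric(1))
  x <- log(1 / vapply(ms, function(m) log_distance(m$concentration, rho_c),
                      numeric(1)))
  fit <- weighted_linear_fit(x, log(y), log_err(y, yerr))
  structure(list(per_k = list(mean_size = fit), phi = NULL, phi_err = NULL,
                 m = fit$slope, m_err = fit$slope_err,
                 alpha = 1 - fit$slope / phi_used, phi_used = phi_used,
                 k_grid = 1, rho_c_used = rho_c,
                 exclusions = exclusions %||% series$excluded %||% numeric()),
            class = "exponent_fit")
}

#' @export
print.exponent_fit <- function(x, ...) {
  cat("<exponent_fit>\n")
  if (!is.null(x$phi))
    cat(sprintf("  phi   = %.4f +/- %.4f  (pooled over k = %s)\n",
                x$phi, x$phi_err, paste(x$k_grid, collapse = ", ")))
  if (!is.null(x$m))
    cat(sprintf("  m     = %.4f +/- %.4f\n  alpha = %.4f  (phi_used = %g)\n",
                x$m, x$m_err, x$alpha, x$phi_used))
  invisible(x)
}

#' Choose moment orders by linearity of the moment-ratio regression
#'
#' Scores every candidate k by the weighted r-squared of its moment-ratio
#' regression against \eqn{\ln(1/|\tilde\rho|)} and returns the `n_select`
#' best, ties broken towards smaller k (so an exactly scaling series
#' returns the first `n_select` candidates in ascending order). The
#' default candidate grid scans k from 0.25 to 3 in steps of 0.25.
#'
#' @inheritParams estimate_phi
#' @param candidates candidate moment orders.
#' @param n_select how many to keep.
#' @return Ascending numeric vector of the selected k values.
#' @export
select_k_grid <- function(series, rho_c, candidates = seq(0.25, 3, by = 0.25),
                          n_select = 4, exclusions = NULL) {
  candidates <- sort(as.numeric(candidates))
  stopifnot(length(candidates) >= 1L, n_select >= 1L,
            n_select <= length(candidates))
  fit <- estimate_phi(series, rho_c, k_grid = candidates,
                      exclusions = exclusions)
  r2 <- vapply(fit$per_k, `[[`, numeric(1), "r_squared")
  ord <- order(-round(r2, 10), candidates)
  sort(candidates[ord[seq_len(n_select)]])
}
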
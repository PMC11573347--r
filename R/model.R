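#' Fit the scaling model to a droplet concentration series
#'
#' The main entry point of the package. Given droplet size tables at
#' several concentrations below the critical concentration, it
#' \enumerate{
#'   \item estimates the critical concentration \eqn{\rho_c} from the
#'     x-axis intercepts of transformed moments (unless `rho_c` is
#'     supplied), see [rhoc_moment_intercept()] / [rhoc_ratio_intercept()];
#'   \item estimates the divergence exponent \eqn{\phi} by pooled
#'     error-weighted log-log regression of the moment ratios against the
#'     inverse distance \eqn{1/|\tilde\rho|}, see [estimate_phi()];
#'   \item estimates the slope m of the mean-size regression and the
#'     prefactor exponent \eqn{\alpha = 1 - m/\phi}, see
#'     [estimate_m_alpha()];
#'   \item fits a log-normal per concentration (location `ln_s0`, width
#'     `sigma`), see [fit_lognormal_series()].
#' }
#'
#' @param series a [concentration_series].
#' @param k_grid moment orders for the ratio and intercept fits (default
#'   the preset `k_grid_preset("fus")`; pass
#'   `select_k_grid()` output to choose by linearity).
#' @param rho_c known critical concentration (uM); `NULL` (default)
#'   estimates it from the data.
#' @param exclude concentrations (uM) excluded from every regression.
#' @param method critical-point estimator used when `rho_c` is `NULL`.
#' @param phi_fixed exponent assumed by the ratio-intercept estimator.
#' @param pooling pooling mode of the critical-point estimate (across
#'   `"k"` or across `"replicate"`s).
#' @param phi_used value of phi in the exponent relation
#'   `alpha = 1 - m/phi_used`; `NULL` (default) uses the fitted pooled
#'   phi, the self-consistent choice.
#' @param variance_mode log-width denominator, see [fit_lognormal()].
#' @return An object of class `droplet_scaling` with components
#'   `rho_c`, `rho_c_err`, `critical_point` (when estimated), `exponents`
#'   (an `exponent_fit` carrying `phi`, `m`, `alpha` and all per-k
#'   regressions), `lognormal` (per-concentration fits), `sigma_bar`,
#'   `a_hat`, `k_grid`, `exclusions`, `call`. Methods: `print`, `summary`,
#'   `coef`, `predict`, `plot`, `simulate`, `residuals`.
#' @examples
#' spec <- synthetic_model_spec(n_droplets = 500, seed = 42)
#' fit <- droplet_scaling(generate_series(spec))
#' coef(fit)
#' predict(fit, rho = 4)   # characteristic size near the critical point
#' @export
droplet_scaling <- function(series, k_grid = k_grid_preset("fus"),
                            rho_c = NULL, exclude = NULL,
                            method = c("moment_intercept", "ratio_intercept"),
                            phi_fixed = 1, pooling = c("k", "replicate"),
                            phi_used = NULL,
                            variance_mode = c("sample", "population")) {
  method <- match.arg(method)
  pooling <- match.arg(pooling)
  variance_mode <- match.arg(variance_mode)
  stopifnot(inherits(series, "concentration_series"))
  k_grid <- sort(as.numeric(k_grid))

  cp <- NULL
  rho_c_err <- NA_real_
  if (is.null(rho_c)) {
    cp <- if (method == "moment_intercept")
      rhoc_moment_intercept(series, k_grid, exclude, pooling)
    else
      rhoc_ratio_intercept(series, k_grid, phi_fixed, exclude, pooling)
    rho_c <- cp$rho_c
    rho_c_err <- cp$rho_c_err
  }

  phi_fit <- estimate_phi(series, rho_c, k_grid, exclude)
  m_fit <- estimate_m_alpha(series, rho_c,
                            phi_used = phi_used %||% phi_fit$phi,
                            exclusions = exclude)
  exponents <- phi_fit
  exponents$m <- m_fit$m
  exponents$m_err <- m_fit$m_err
  exponents$alpha <- m_fit$alpha
  exponents$phi_used <- m_fit$phi_used
  exponents$per_k$mean_size <- m_fit$per_k$mean_size

  ln_fits <- fit_lognormal_series(series, variance_mode)
  # intercept of the k = 1 ratio fit is ln(a) for a log-normal series
  a_hat <- if ("1" %in% names(exponents$per_k))
    exp(exponents$per_k[["1"]]$intercept) else NA_real_

  structure(list(rho_c = rho_c, rho_c_err = rho_c_err,
                 critical_point = cp, exponents = exponents,
                 lognormal = ln_fits,
                 sigma_bar = mean(ln_fits$sigma), a_hat = a_hat,
                 k_grid = k_grid,
                 exclusions = exclude %||% series$excluded %||% numeric(),
                 n_tables = length(series$tables),
                 concentrations = concentrations(series),
                 size_kind = series$tables[[1L]]$size_kind,
                 call = match.call()),
            class = "droplet_scaling")
}

#' @export
print.droplet_scaling <- function(x, ...) {
  cat("Scale-invariant droplet size analysis\n")
  cat(sprintf("  concentrations: %s uM (%d tables)\n",
              paste(format(x$concentrations), collapse = ", "), x$n_tables))
  if (length(x$exclusions))
    cat("  excluded:", paste(x$exclusions, collapse = ", "), "uM\n")
  src <- if (is.null(x$critical_point)) "supplied"
         else paste0("estimated, ", x$critical_point$method)
  cat(sprintf("  rho_c = %.4g%s uM  (%s)\n", x$rho_c,
              if (is.finite(x$rho_c_err))
                sprintf(" +/- %.2g", x$rho_c_err) else "", src))
  cat(sprintf("  phi   = %.4f +/- %.4f\n", x$exponents$phi,
              x$exponents$phi_err))
  cat(sprintf("  m     = %.4f +/- %.4f,  alpha = %.4f\n",
              x$exponents$m, x$exponents$m_err, x$exponents$alpha))
  invisible(x)
}

#' @export
summary.droplet_scaling <- function(object, ...) {
  per_k <- data.frame(
    k = object$exponents$k_grid,
    phi_k = vapply(object$exponents$per_k[as.character(object$exponents$k_grid)],
                   `[[`, numeric(1), "slope"),
    phi_k_err = vapply(object$exponents$per_k[as.character(object$exponents$k_grid)],
                       `[[`, numeric(1), "slope_err"),
    r_squared = vapply(object$exponents$per_k[as.character(object$exponents$k_grid)],
                       `[[`, numeric(1), "r_squared"))
  structure(list(fit = object, per_k = per_k,
                 lognormal = object$lognormal,
                 per_intercept = if (!is.null(object$critical_point))
                   object$critical_point$per_fit),
            class = "summary.droplet_scaling")
}

#' @export
print.summary.droplet_scaling <- function(x, ...) {
  print(x$fit)
  cat("\nPer-k moment-ratio regressions (slope = phi_k):\n")
  print(x$per_k, row.names = FALSE, digits = 4)
  cat("\nPer-concentration log-normal fits:\n")
  print(x$lognormal, row.names = FALSE, digits = 4)
  if (!is.null(x$per_intercept)) {
    cat("\nPer-fit critical-concentration intercepts:\n")
    print(x$per_intercept, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
coef.droplet_scaling <- function(object, ...) {
  c(phi = object$exponents$phi, m = object$exponents$m,
    alpha = object$exponents$alpha, rho_c = object$rho_c)
}

#' Predict the characteristic droplet size at new concentrations
#'
#' Uses the fitted k = 1 moment-ratio regression — for which the ratio
#' \eqn{\langle s^2\rangle/\langle s\rangle} equals the characteristic
#' size exactly — to predict \eqn{s_c(\rho)} at subsaturated
#' concentrations.
#'
#' @param object a [droplet_scaling] fit whose `k_grid` contains 1.
#' @param rho concentrations (uM), each in (0, rho_c).
#' @param ... unused.
#' @return Numeric vector of predicted characteristic sizes.
#' @export
predict.droplet_scaling <- function(object, rho, ...) {
  fit <- object$exponents$per_k[["1"]]
  if (is.null(fit))
    stop("prediction needs k = 1 in the fitted k_grid (the k = 1 moment ",
         "ratio is the characteristic size)", call. = FALSE)
  exp(fit$intercept + fit$slope * log(1 / log_distance(rho, object$rho_c)))
}

#' Simulate series from a fitted scaling model
#'
#' Draws synthetic concentration series from the generative model implied
#' by the fit: log-normal sizes with the fitted mean log-width, a
#' characteristic size diverging with the fitted phi at the fitted
#' rho_c, and amplitude taken from the k = 1 ratio intercept. Parametric
#'-bootstrap style replicas of the experiment.
#'
#' @param object a [droplet_scaling] fit.
#' @param nsim number of series.
#' @param seed integer seed.
#' @param n_droplets,n_replicates structure of each simulated series
#'   (defaults mirror typical usage).
#' @param ... unused.
#' @return A list of `nsim` [concentration_series] objects.
#' @export
simulate.droplet_scaling <- function(object, nsim = 1, seed = 1L,
                                     n_droplets = 5000L, n_replicates = 3L,
                                     ...) {
  if (!is.finite(object$a_hat))
    stop("simulation needs k = 1 in the fitted k_grid", call. = FALSE)
  conc <- setdiff(object$concentrations, object$exclusions)
  lapply(seq_len(nsim), function(i) {
    generate_series(synthetic_model_spec(
      rho_c = object$rho_c, a = object$a_hat, phi = object$exponents$phi,
      sigma = object$sigma_bar, concentrations = conc,
      n_droplets = n_droplets, n_replicates = n_replicates,
      seed = as.integer(seed) + i - 1L))
  })
}

#' @export
residuals.droplet_scaling <- function(object, ...) {
  sapply(object$exponents$per_k, `[[`, "residuals")
}

#' Diagnostic plots of a scaling fit
#'
#' Two panels: the moment-ratio regressions in double-logarithmic
#' coordinates (slopes = phi_k), and — when the critical point was
#' estimated by moment intercepts — the transformed moments against
#' concentration with their fitted lines crossing the x-axis at the
#' estimated critical concentration.
#'
#' @param x a [droplet_scaling] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.droplet_scaling <- function(x, ...) {
  ks <- as.character(x$exponents$k_grid)
  fits <- x$exponents$per_k[ks]
  two <- !is.null(x$critical_point) &&
    x$critical_point$method == "moment_intercept" &&
    x$critical_point$pooling == "k"
  if (two) {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  xs <- unlist(lapply(fits, `[[`, "x"))
  ys <- unlist(lapply(fits, `[[`, "y"))
  cols <- grDevices::hcl.colors(length(fits), "Dark 2")
  graphics::plot(range(xs), range(ys), type = "n",
                 xlab = expression(ln(1 / abs(tilde(rho)))),
                 ylab = expression(ln(group(langle, s^{k + 1}, rangle) /
                                        group(langle, s^k, rangle))),
                 main = "Moment-ratio scaling", ...)
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    graphics::points(f$x, f$y, col = cols[i], pch = 19)
    graphics::abline(f$intercept, f$slope, col = cols[i])
  }
  graphics::legend("topleft", legend = paste("k =", ks), col = cols,
                   pch = 19, bty = "n")
  if (two) {
    pf <- x$critical_point$per_fit
    conc <- x$concentrations
    graphics::plot(NA, xlim = c(0, x$rho_c * 1.05),
                   ylim = c(0, max(-pf$slope * 0 + pf$intercept)),
                   xlab = expression(rho ~ "(uM)"),
                   ylab = expression(group(langle, s^k, rangle)^{-1 / k}),
                   main = "Moment-intercept estimate")
    for (i in seq_len(nrow(pf)))
      graphics::abline(pf$intercept[i], pf$slope[i],
                       col = cols[(i - 1L) %% length(cols) + 1L])
    graphics::abline(h = 0, lty = 3)
    graphics::abline(v = x$rho_c, lty = 2)
    graphics::mtext(sprintf("rho_c = %.3g uM", x$rho_c), side = 3,
                    line = -1.5, cex = 0.8)
  }
  invisible(x)
}
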
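#' Critical concentration from moment intercepts
#'
#' The scaling ansatz with phi = 1 predicts that
#' \eqn{\langle s^k\rangle^{-1/k}} is a straight line in the concentration
#' \eqn{\rho},
#' \deqn{\langle s^k\rangle^{-1/k} =
#'   \frac{1}{a} e^{(3-k)\sigma^2/2}\,\frac{\rho_c-\rho}{\rho_c},}
#' which crosses the x-axis at the critical concentration regardless of k.
#' For each k the transformed moments are fitted by error-weighted linear
#' regression (moment standard errors moved through the power by the delta
#' method) and the intercept \eqn{\rho_{c,i} = -q/m} is read off; the
#' pooled estimate is the mean of the \eqn{\rho_{c,i}}.
#'
#' Two pooling modes reflect the two experimental designs the method has
#' been applied to: `"k"` pools across moment orders computed on
#' replicate-averaged moments (the spread across k estimates the error);
#' `"replicate"` fits each replicate separately, averages the per-k
#' intercepts within a replicate, and pools across replicates with a
#' standard error of the mean.
#'
#' @param series a [concentration_series], or a list of `moment_set`
#'   objects (e.g. [exact_moment_series()]; `"k"` pooling only).
#' @param k_grid moment orders.
#' @param exclusions concentrations to drop (`NULL` defers to the series).
#' @param pooling `"k"` or `"replicate"`.
#' @return An object of class `critical_point_estimate`: `method`,
#'   `per_fit` (data frame with one row per fitted line: `k`, `replicate`,
#'   `slope`, `intercept`, `slope_err`, `intercept_err`, `rho_c_i`,
#'   `rho_c_i_err`), `rho_c`, `rho_c_err`, `k_grid`, `pooling`.
#' @export
rhoc_moment_intercept <- function(series, k_grid = k_grid_preset("fus"),
                                  exclusions = NULL,
                                  pooling = c("k", "replicate")) {
  pooling <- match.arg(pooling)
  k_grid <- sort(as.numeric(k_grid))
  if (length(k_grid) == 0L || any(k_grid <= 0))
    stop("k_grid must be non-empty and positive", call. = FALSE)
  transform <- function(m, err, k) {
    y <- m^(-1 / k)
    list(y = y, err = abs(y / (k * m)) * err)   # |dy/dm| = y/(k m)
  }
  rhoc_intercept_engine(series, k_grid, exclusions, pooling, transform,
                        method = "moment_intercept", phi_fixed = NULL)
}

#' Critical concentration from moment-ratio intercepts
#'
#' Alternative estimator based on the ratio to the first moment:
#' \eqn{(\langle s^k\rangle/\langle s\rangle)^{-1/(k-1)}} is proportional
#' to \eqn{1/s_c = |\tilde\rho|^{\phi}/a}, so with `phi_fixed = 1` it is
#' fitted as a straight line in \eqn{\rho} whose x-intercept \eqn{-q/m}
#' estimates the critical concentration; the unknown prefactor cancels in
#' the intercept. For `phi_fixed != 1` the transformed quantity is raised
#' to `1/phi_fixed` before the linear fit. `form = "hyperbolic"` instead
#' fits the variant that normalizes the distance by \eqn{\rho} rather than
#' \eqn{\rho_c} (multiplying through by \eqn{\rho} keeps the fit linear);
#' near the critical point the two agree to first order and both vanish at
#' \eqn{\rho_c}.
#'
#' @inheritParams rhoc_moment_intercept
#' @param k_grid moment orders, all different from 1.
#' @param phi_fixed exponent assumed for the divergence (default 1).
#' @param form `"linear"` (distance normalized by rho_c) or
#'   `"hyperbolic"` (normalized by rho).
#' @return A `critical_point_estimate` (see [rhoc_moment_intercept()]).
#' @export
rhoc_ratio_intercept <- function(series, k_grid = k_grid_preset("asyn"),
                                 phi_fixed = 1, exclusions = NULL,
                                 pooling = c("k", "replicate"),
                                 form = c("linear", "hyperbolic")) {
  pooling <- match.arg(pooling)
  form <- match.arg(form)
  k_grid <- sort(as.numeric(k_grid))
  if (length(k_grid) == 0L || any(k_grid <= 0))
    stop("k_grid must be non-empty and positive", call. = FALSE)
  if (any(k_grid == 1))
    stop("ratio_intercept requires all k != 1 (the ratio to <s> degenerates ",
         "at k = 1)", call. = FALSE)
  stopifnot(phi_fixed > 0)
  transform <- function(ratio, err, k) {
    e <- -1 / ((k - 1) * phi_fixed)
    y <- ratio^e
    list(y = y, err = abs(e * y / ratio) * err)
  }
  rhoc_intercept_engine(series, k_grid, exclusions, pooling, transform,
                        method = "ratio_intercept", phi_fixed = phi_fixed,
                        use_ratio = TRUE, form = form)
}

# Shared machinery of the two intercept estimators: build per-(k [, rep])
# transformed series, WLS-fit against concentration, read off -q/m, pool.
rhoc_intercept_engine <- function(series, k_grid, exclusions, pooling,
                                  transform, method, phi_fixed,
                                  use_ratio = FALSE, form = "linear") {
  k_need <- if (use_ratio) unique(c(k_grid, 1)) else k_grid
  ms <- moments_for_cp(series, k_need, exclusions)
  conc <- vapply(ms, `[[`, numeric(1), "concentration")

  fit_one <- function(k, values, errs, replicate = NA_integer_) {
    tr <- transform(values, errs, k)
    x <- conc; y <- tr$y; yerr <- tr$err
    if (form == "hyperbolic") {       # y = C (rho_c - rho)/rho  =>  y*rho linear in rho
      y <- tr$y * conc
      yerr <- tr$err * conc
    }
    fit <- weighted_linear_fit(x, y, yerr)
    if (fit$slope >= 0)
      stop("no x-axis crossing above the data: fitted slope is ",
           signif(fit$slope, 4), " >= 0 for k = ", k,
           "; the series does not show the decreasing trend expected in ",
           "the scaling regime", call. = FALSE)
    rc <- -fit$intercept / fit$slope
    # delta-method error of -q/m from the parameter covariance
    var_rc <- fit$intercept_err^2 / fit$slope^2 +
      fit$intercept^2 * fit$slope_err^2 / fit$slope^4 -
      2 * fit$intercept * fit$cov_ab / fit$slope^3
    data.frame(k = k, replicate = replicate, slope = fit$slope,
               intercept = fit$intercept, slope_err = fit$slope_err,
               intercept_err = fit$intercept_err, rho_c_i = rc,
               rho_c_i_err = sqrt(max(var_rc, 0)))
  }

  value_of <- function(m_k, m_1) if (use_ratio) m_k / m_1 else m_k
  if (pooling == "k") {
    rows <- lapply(k_grid, function(k) {
      vals <- vapply(ms, function(m) {
        value_of(moment_at(m, k)$mean,
                 if (use_ratio) moment_at(m, 1)$mean else NULL)
      }, numeric(1))
      errs <- vapply(ms, function(m) {
        if (use_ratio) moment_ratio_k1(m, k)$error else moment_at(m, k)$err
      }, numeric(1))
      fit_one(k, vals, errs)
    })
    per_fit <- do.call(rbind, rows)
    rho_c <- mean(per_fit$rho_c_i)
    rho_c_err <- if (nrow(per_fit) > 1L) stats::sd(per_fit$rho_c_i) else 0
  } else {
    n_rep <- unique(vapply(ms, `[[`, integer(1), "n_replicates"))
    if (length(n_rep) != 1L)
      stop("replicate pooling needs the same replicate count at every ",
           "concentration", call. = FALSE)
    if (n_rep < 2L)
      stop("replicate pooling needs >= 2 replicates", call. = FALSE)
    rows <- lapply(seq_len(n_rep), function(ri) {
      do.call(rbind, lapply(k_grid, function(k) {
        vals <- vapply(ms, function(m) {
          rk <- m$replicate_moments[ri, match_k(m$k, k)]
          if (use_ratio) rk / m$replicate_moments[ri, match_k(m$k, 1)] else rk
        }, numeric(1))
        fit_one(k, vals, rep(0, length(vals)), replicate = ri)
      }))
    })
    per_fit <- do.call(rbind, rows)
    per_rep <- vapply(split(per_fit$rho_c_i, per_fit$replicate), mean,
                      numeric(1))
    rho_c <- mean(per_rep)
    rho_c_err <- stats::sd(per_rep) / sqrt(length(per_rep))
  }
  structure(list(method = method, per_fit = per_fit, rho_c = rho_c,
                 rho_c_err = rho_c_err, k_grid = k_grid,
                 phi_fixed = phi_fixed, pooling = pooling, form = form),
            class = "critical_point_estimate")
}

# Ratio <s^k>/<s> with propagated replicate error (independence assumed).
moment_ratio_k1 <- function(ms, k) {
  num <- moment_at(ms, k); den <- moment_at(ms, 1)
  value <- num$mean / den$mean
  list(value = value,
       error = value * sqrt((num$err / num$mean)^2 + (den$err / den$mean)^2))
}

moments_for_cp <- function(series, k_need, exclusions) {
  if (is_moment_set_list(series)) {
    ms <- series
    if (!is.null(exclusions) && length(exclusions))
      ms <- Filter(function(m) !(m$concentration %in% exclusions), ms)
  } else {
    stopifnot(inherits(series, "concentration_series"))
    ms <- moment_sets(apply_exclusions(series, exclusions), k_need)
  }
  if (length(ms) < 2L)
    stop("insufficient data: need >= 2 non-excluded concentrations",
         call. = FALSE)
  ms
}

#' @export
print.critical_point_estimate <- function(x, ...) {
  cat(sprintf(
    "<critical_point_estimate> %s: rho_c = %.4g +/- %.3g uM (pooled over %s)\n",
    x$method, x$rho_c, x$rho_c_err,
    if (x$pooling == "k") paste0("k = ", paste(x$k_grid, collapse = ", "))
    else "replicates"))
  invisible(x)
}

#' Run the configured critical-point estimator
#'
#' Dispatches on `config$method`; with `method = "both"` runs the
#' moment-intercept and ratio-intercept estimators and returns both, so
#' their agreement can serve as an internal consistency check.
#'
#' @param series a [concentration_series] or list of `moment_set`s.
#' @param config an [analysis_config].
#' @param method override of `config$method`; one of
#'   `"moment_intercept"`, `"ratio_intercept"`, `"both"`.
#' @return A `critical_point_estimate`, or for `"both"` a named list of
#'   two.
#' @export
rhoc_pipeline <- function(series, config = analysis_config(), method = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  method <- method %||% config$method
  run <- function(m) switch(
    m,
    moment_intercept = rhoc_moment_intercept(
      series, k_grid = config$k_grid, exclusions = config$exclusions,
      pooling = config$pooling),
    ratio_intercept = rhoc_ratio_intercept(
      series, k_grid = config$k_grid, phi_fixed = config$phi_fixed,
      exclusions = config$exclusions, pooling = config$pooling),
    stop("unknown method: ", m, call. = FALSE))
  if (identical(method, "both"))
    list(moment_intercept = run("moment_intercept"),
         ratio_intercept = run("ratio_intercept"))
  else run(method)
}
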
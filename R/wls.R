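#' Error-weighted linear fit
#'
#' Minimizes \eqn{\sum_i w_i (y_i - a - b x_i)^2} with weights
#' \eqn{w_i = 1/\mathrm{err}(y_i)^2}, the regression used throughout the
#' scaling analysis. With known per-point errors the parameter standard
#' errors come from the weighted normal equations
#' (\eqn{\mathrm{var}(b) = S_w/\Delta},
#' \eqn{\mathrm{var}(a) = S_{wxx}/\Delta},
#' \eqn{\Delta = S_w S_{wxx} - S_{wx}^2}), i.e. they do not rescale with
#' the residuals. If any error is zero or errors are omitted, uniform
#' weights are used (flagged in the result) and the standard errors fall
#' back to the residual-based ordinary-least-squares ones.
#'
#' @param x,y coordinates (length >= 2).
#' @param y_err per-point errors of `y`; `NULL` or any zero entry triggers
#'   the uniform-weight fallback.
#' @return An object of class `wls_fit`: `slope`, `intercept`,
#'   `slope_err`, `intercept_err`, `cov_ab` (slope/intercept covariance),
#'   `r_squared` (weighted), `n_points`, `uniform_weights`, plus the data.
#' @export
weighted_linear_fit <- function(x, y, y_err = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n < 2L || length(y) != n)
    stop("need matching x and y of length >= 2", call. = FALSE)
  if (!is.null(y_err) && length(y_err) != n)
    stop("y_err must match x and y in length", call. = FALSE)
  if (max(x) - min(x) <= 0)
    stop("singular design: all x identical", call. = FALSE)
  uniform <- is.null(y_err) || any(y_err <= 0) || any(!is.finite(y_err))
  w <- if (uniform) rep(1, n) else 1 / y_err^2
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  delta <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / delta
  intercept <- (swxx * swy - swx * swxy) / delta
  res <- y - intercept - slope * x
  if (uniform) {
    # residual-based scale (OLS); zero when the fit is exact or n = 2
    s2 <- if (n > 2L) sum(w * res^2) / (n - 2L) else 0
    var_b <- s2 * sw / delta
    var_a <- s2 * swxx / delta
    cov_ab <- -s2 * swx / delta
  } else {
    var_b <- sw / delta
    var_a <- swxx / delta
    cov_ab <- -swx / delta
  }
  ybar <- swy / sw
  tss <- sum(w * (y - ybar)^2)
  r2 <- if (tss > 0) 1 - sum(w * res^2) / tss else 1
  structure(list(slope = slope, intercept = intercept,
                 slope_err = sqrt(var_b), intercept_err = sqrt(var_a),
                 cov_ab = cov_ab, r_squared = r2, n_points = n,
                 uniform_weights = uniform,
                 x = x, y = y, y_err = y_err, residuals = res),
            class = "wls_fit")
}

#' @export
print.wls_fit <- function(x, ...) {
  cat(sprintf(
    "<wls_fit> slope = %.5g (+/- %.3g), intercept = %.5g (+/- %.3g), r2 = %.4f, n = %d%s\n",
    x$slope, x$slope_err, x$intercept, x$intercept_err, x$r_squared,
    x$n_points, if (x$uniform_weights) " [uniform weights]" else ""))
  invisible(x)
}
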
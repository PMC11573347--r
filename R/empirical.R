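#' Empirical survival distribution function of droplet sizes
#'
#' \eqn{P_>(x) = N_{>x}/N_{tot}}: the fraction of droplets strictly larger
#' than `x`, evaluated at the table's distinct sizes with counts respected
#' as multiplicities. Ties at a threshold count as not surviving
#' (strictly-greater convention).
#'
#' @param table a [droplet_table].
#' @return An object of class `sdf_curve` with fields `thresholds`
#'   (ascending sizes), `survival` (non-increasing, in `[0, 1]`) and
#'   `n_total`.
#' @seealso [sdf_eval()] to evaluate the step function at arbitrary points.
#' @export
empirical_sdf <- function(table) {
  stopifnot(inherits(table, "droplet_table"))
  agg <- rowsum(table$count, group = table$size)
  thresholds <- as.numeric(rownames(agg))
  counts <- unname(agg[, 1L])
  n_tot <- sum(counts)
  # N_{> t_i} = total mass above threshold i
  survival <- (n_tot - cumsum(counts)) / n_tot
  structure(list(thresholds = thresholds, survival = survival,
                 n_total = n_tot),
            class = "sdf_curve")
}

#' Evaluate an empirical SDF at arbitrary points
#'
#' The empirical survival function is piecewise constant and
#' right-continuous: for `x` between two observed sizes it equals the value
#' at the largest observed size not exceeding `x`; below the smallest size
#' it is 1.
#'
#' @param curve an `sdf_curve` from [empirical_sdf()].
#' @param x evaluation points.
#' @return Numeric vector of survival probabilities.
#' @export
sdf_eval <- function(curve, x) {
  idx <- findInterval(x, curve$thresholds)
  c(1, curve$survival)[idx + 1L]
}

#' @export
print.sdf_curve <- function(x, ...) {
  cat(sprintf("<sdf_curve> %d thresholds, %g droplets\n",
              length(x$thresholds), x$n_total))
  invisible(x)
}

#' Fractional sample moment of a droplet table
#'
#' \eqn{\langle s^k\rangle = \sum_i c_i s_i^k / \sum_i c_i} with counts
#' \eqn{c_i} as multiplicities. Powers are accumulated in log space
#' (log-sum-exp), so wide size ranges and large fractional `k` do not
#' overflow intermediate terms; a non-finite final value is an error.
#'
#' @param table a [droplet_table].
#' @param k moment order(s), each > 0 (the limit k -> 0 gives 1).
#' @return Numeric vector, one moment per element of `k`.
#' @export
size_moment <- function(table, k) {
  stopifnot(inherits(table, "droplet_table"))
  if (any(k < 0)) stop("moment order k must be >= 0", call. = FALSE)
  ls <- log(table$size)
  lc <- log(table$count)
  ln <- log(sum(table$count))
  out <- vapply(k, function(kk) exp(logsumexp(lc + kk * ls) - ln), numeric(1))
  if (any(!is.finite(out)))
    stop("moment overflow: non-finite <s^k> for k = ",
         paste(k[!is.finite(out)], collapse = ", "), call. = FALSE)
  out
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# -- moment sets over replicates ---------------------------------------------

new_moment_set <- function(concentration, k, mean, err, n_replicates,
                           replicate_moments) {
  structure(list(concentration = concentration, k = k, mean = mean,
                 err = err, n_replicates = n_replicates,
                 replicate_moments = replicate_moments),
            class = "moment_set")
}

#' @export
print.moment_set <- function(x, ...) {
  cat(sprintf("<moment_set> at %g uM over %d replicate(s)\n",
              x$concentration, x$n_replicates))
  print(data.frame(k = x$k, mean = x$mean, sem = x$err))
  invisible(x)
}

#' Replicate-averaged fractional moments per concentration
#'
#' For each concentration in the series, computes \eqn{\langle s^k\rangle}
#' per replicate and reports the mean over replicates together with the
#' standard error of the mean (0, flagged by `n_replicates = 1`, when only
#' one replicate exists). This is the averaging step behind every
#' error-weighted regression in the package.
#'
#' @param series a [concentration_series] (or a list of precomputed
#'   `moment_set` objects, returned unchanged — the analytic moments of
#'   [exact_moment_series()] plug in here).
#' @param k_grid moment orders.
#' @return List of `moment_set` objects, one per concentration in
#'   ascending order.
#' @export
moment_sets <- function(series, k_grid) {
  if (is_moment_set_list(series)) return(series)
  stopifnot(inherits(series, "concentration_series"))
  k_grid <- sort(unique(as.numeric(k_grid)))
  lapply(concentrations(series), function(rho) {
    tabs <- tables_at(series, rho)
    reps <- t(vapply(tabs, size_moment, numeric(length(k_grid)), k = k_grid))
    if (length(k_grid) == 1L) reps <- matrix(reps, ncol = 1L)
    colnames(reps) <- k_grid
    n <- nrow(reps)
    mean_m <- unname(colMeans(reps))
    err <- if (n > 1L) unname(apply(reps, 2L, stats::sd)) / sqrt(n)
           else rep(0, length(k_grid))
    new_moment_set(concentration = rho, k = k_grid, mean = mean_m, err = err,
                   n_replicates = n, replicate_moments = reps)
  })
}

is_moment_set_list <- function(x) {
  is.list(x) && length(x) > 0L &&
    all(vapply(x, inherits, logical(1), "moment_set"))
}

moment_at <- function(ms, k) {
  i <- match_k(ms$k, k)
  list(mean = ms$mean[i], err = ms$err[i])
}

match_k <- function(k_values, k) {
  i <- which(abs(k_values - k) < 1e-9)
  if (length(i) != 1L)
    stop("moment order k = ", k, " not available in the moment set",
         call. = FALSE)
  i
}

#' Ratio of consecutive moments with propagated error
#'
#' \eqn{\langle s^{k+1}\rangle/\langle s^k\rangle}, the quantity whose
#' log-log slope against the inverse distance from the critical
#' concentration is the exponent phi. The error is first-order propagation
#' from the two replicate standard errors, treated as independent.
#'
#' @param ms a `moment_set` containing both `k` and `k + 1`.
#' @param k moment order.
#' @return List with `value` and `error`.
#' @export
moment_ratio <- function(ms, k) {
  stopifnot(inherits(ms, "moment_set"))
  num <- moment_at(ms, k + 1)
  den <- moment_at(ms, k)
  value <- num$mean / den$mean
  error <- value * sqrt((num$err / num$mean)^2 + (den$err / den$mean)^2)
  list(value = value, error = error)
}

# -- log-normal forms ---------------------------------------------------------

#' Log-normal fit of one droplet table
#'
#' Moment estimates in log space: `ln_s0` is the (count-weighted) mean of
#' `ln(s)` and `sigma` its standard deviation, using the n-1 denominator in
#' `"sample"` mode and n in `"population"` mode (n = total droplet count).
#' The derived characteristic size is \eqn{s_c = s_0 e^{3\sigma^2/2}},
#' the ratio of the second to the first moment of the fitted law. Standard
#' errors are the normal-theory ones in log space
#' (\eqn{\sigma/\sqrt n} and \eqn{\sigma/\sqrt{2n}}).
#'
#' @param table a [droplet_table] with at least two distinct sizes.
#' @param variance_mode `"sample"` or `"population"`.
#' @param allow_degenerate if `TRUE`, a single distinct size returns
#'   `sigma = 0` instead of an error (oracle checks only).
#' @return An object of class `lognormal_fit` with fields `concentration`,
#'   `ln_s0`, `sigma`, `s_c_derived`, `ln_s0_err`, `sigma_err`, `n`.
#' @export
fit_lognormal <- function(table, variance_mode = c("sample", "population"),
                          allow_degenerate = FALSE) {
  variance_mode <- match.arg(variance_mode)
  stopifnot(inherits(table, "droplet_table"))
  if (length(unique(table$size)) < 2L && !allow_degenerate)
    stop("degenerate distribution: need >= 2 distinct sizes to estimate sigma",
         call. = FALSE)
  n <- sum(table$count)
  w <- table$count / n
  ls <- log(table$size)
  ln_s0 <- sum(w * ls)
  ss <- sum(w * (ls - ln_s0)^2)
  if (variance_mode == "sample" && n > 1) ss <- ss * n / (n - 1)
  sigma <- sqrt(ss)
  structure(list(concentration = table$concentration,
                 ln_s0 = ln_s0, sigma = sigma,
                 s_c_derived = exp(ln_s0 + 1.5 * sigma^2),
                 ln_s0_err = sigma / sqrt(n),
                 sigma_err = sigma / sqrt(2 * n),
                 n = n, variance_mode = variance_mode),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf(
    "<lognormal_fit> at %g uM: ln s0 = %.4f (+/- %.4f), sigma = %.4f (+/- %.4f), s_c = %.4g\n",
    x$concentration, x$ln_s0, x$ln_s0_err, x$sigma, x$sigma_err,
    x$s_c_derived))
  invisible(x)
}

#' Per-concentration log-normal fits with replicate errors
#'
#' Fits each replicate table separately and reports, per concentration,
#' the replicate means of `ln_s0` and `sigma` with their standard errors —
#' the quantities whose flatness in concentration (for sigma) underpins
#' the scale-invariance of the distribution.
#'
#' @param series a [concentration_series].
#' @param variance_mode see [fit_lognormal()].
#' @return `data.frame` with one row per concentration: `concentration`,
#'   `ln_s0`, `ln_s0_err`, `sigma`, `sigma_err`, `s_c_derived`,
#'   `n_replicates`.
#' @export
fit_lognormal_series <- function(series,
                                 variance_mode = c("sample", "population")) {
  variance_mode <- match.arg(variance_mode)
  stopifnot(inherits(series, "concentration_series"))
  rows <- lapply(concentrations(series), function(rho) {
    fits <- lapply(tables_at(series, rho), fit_lognormal,
                   variance_mode = variance_mode)
    ln_s0 <- vapply(fits, `[[`, numeric(1), "ln_s0")
    sigma <- vapply(fits, `[[`, numeric(1), "sigma")
    n <- length(fits)
    sem <- function(v) if (n > 1L) stats::sd(v) / sqrt(n) else 0
    data.frame(concentration = rho,
               ln_s0 = mean(ln_s0), ln_s0_err = sem(ln_s0),
               sigma = mean(sigma), sigma_err = sem(sigma),
               s_c_derived = exp(mean(ln_s0) + 1.5 * mean(sigma)^2),
               n_replicates = n)
  })
  do.call(rbind, rows)
}

#' Survival function of the log-normal size distribution
#'
#' \eqn{P_>(s) = \tfrac12\,\mathrm{erfc}\!\big(\ln(s/s_0)/(\sigma\sqrt2)\big)}.
#'
#' @param s size(s), > 0.
#' @param s0 median size, > 0.
#' @param sigma log-scale width, > 0.
#' @return Survival probabilities in `[0, 1]`.
#' @export
lognormal_sdf <- function(s, s0, sigma) {
  stopifnot(all(s > 0), s0 > 0, sigma > 0)
  # erfc(x) = 2 * pnorm(-x * sqrt(2))
  stats::pnorm(log(s / s0) / sigma, lower.tail = FALSE)
}

#' Analytic moments of the log-normal size distribution
#'
#' \eqn{\langle s^k\rangle = s_c^k\,e^{\sigma^2 k(k-3)/2}} where
#' \eqn{s_c = s_0 e^{3\sigma^2/2}} is the characteristic size. Setting
#' `k = 1` and `k = 2` shows \eqn{\langle s^2\rangle/\langle s\rangle = s_c}
#' identically in sigma — the identity that makes the moment ratio a clean
#' gauge of the characteristic size.
#'
#' @param s_c characteristic size, > 0.
#' @param sigma log-scale width, >= 0.
#' @param k moment order(s).
#' @return Numeric vector of moments.
#' @export
lognormal_moment <- function(s_c, sigma, k) {
  stopifnot(all(s_c > 0), all(sigma >= 0))
  s_c^k * exp(sigma^2 * k * (k - 3) / 2)
}

#' Empirical characteristic size
#'
#' The ratio of the second to the first sample moment,
#' \eqn{\langle s^2\rangle/\langle s\rangle} — the model-free estimate of
#' the characteristic droplet size.
#'
#' @param table a [droplet_table].
#' @return Positive number.
#' @export
characteristic_size_empirical <- function(table) {
  m <- size_moment(table, c(1, 2))
  m[2L] / m[1L]
}
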
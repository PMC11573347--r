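#' Standardize log-sizes against a log-normal fit
#'
#' \eqn{z_i = \ln(s_i/s_0)/\sigma}. If the sizes are log-normal the
#' standardized values are standard normal, so empirical SDFs of `z` from
#' all concentrations fall on the single master curve
#' \eqn{\tfrac12\,\mathrm{erfc}(z/\sqrt2)} — the data collapse that
#' evidences log-normal behaviour.
#'
#' @param table a [droplet_table].
#' @param fit a `lognormal_fit` for the same concentration (defaults to
#'   fitting the table itself).
#' @return A [droplet_table]-like object is not returned; rather a list
#'   with `z` (standardized values, ascending) and `count`
#'   (multiplicities).
#' @export
standardize_log <- function(table, fit = fit_lognormal(table)) {
  stopifnot(inherits(table, "droplet_table"), inherits(fit, "lognormal_fit"))
  if (fit$sigma <= 0)
    stop("degenerate fit: sigma = 0, cannot standardize", call. = FALSE)
  list(z = (log(table$size) - fit$ln_s0) / fit$sigma, count = table$count)
}

# Kolmogorov-Smirnov distance between a weighted sample's survival
# function and a continuous reference survival function.
weighted_ks <- function(z, w, ref_survival) {
  ord <- order(z)
  z <- z[ord]; w <- w[ord] / sum(w)
  agg <- rowsum(w, group = z)
  zu <- as.numeric(rownames(agg)); wu <- agg[, 1L]
  s_right <- 1 - cumsum(wu)          # P(> z_i)
  s_left <- s_right + wu             # limit from below
  ref <- ref_survival(zu)
  max(abs(s_right - ref), abs(s_left - ref))
}

new_collapse_result <- function(mode, per_concentration, reference) {
  structure(list(mode = mode, per_concentration = per_concentration,
                 max_distance = max(per_concentration$distance),
                 reference = reference),
            class = "collapse_result")
}

#' @export
print.collapse_result <- function(x, ...) {
  cat(sprintf("<collapse_result> mode = %s, reference = %s\n", x$mode,
              x$reference))
  print(x$per_concentration, row.names = FALSE)
  cat(sprintf("  max distance: %.4f\n", x$max_distance))
  invisible(x)
}

#' Quantify collapse onto the log-normal master curve
#'
#' Per concentration, replicate tables are pooled, a log-normal is fitted,
#' sizes are standardized with [standardize_log()], and the
#' Kolmogorov-Smirnov distance between the standardized empirical SDF and
#' the standard-normal survival function is reported. Small distances at
#' every concentration mean the distributions collapse onto one log-normal
#' master curve; the statistic is invariant under a global rescaling of
#' the sizes.
#'
#' @param series a [concentration_series] with at least two
#'   concentrations (a single concentration is accepted and reduces to a
#'   one-sample KS distance).
#' @param variance_mode see [fit_lognormal()].
#' @return A `collapse_result` with one distance per concentration and
#'   their maximum.
#' @export
collapse_lognormal <- function(series,
                               variance_mode = c("sample", "population")) {
  variance_mode <- match.arg(variance_mode)
  stopifnot(inherits(series, "concentration_series"))
  rows <- lapply(concentrations(series), function(rho) {
    tab <- pool_tables(tables_at(series, rho))
    std <- standardize_log(tab, fit_lognormal(tab, variance_mode))
    data.frame(concentration = rho,
               distance = weighted_ks(std$z, std$count,
                                      function(z) stats::pnorm(z,
                                                               lower.tail = FALSE)))
  })
  new_collapse_result("lognormal_standardize", do.call(rbind, rows),
                      "standard normal survival 0.5*erfc(z/sqrt(2))")
}

# Sup distance between two empirical SDF step functions. Both are
# right-continuous with jumps at their thresholds, so the supremum is
# attained on the union of the jump points.
sdf_sup_distance <- function(c1, c2) {
  grid <- sort(unique(c(c1$thresholds, c2$thresholds)))
  max(abs(sdf_eval(c1, grid) - sdf_eval(c2, grid)))
}

#' Quantify collapse under rescaling by the distance from criticality
#'
#' If the scaling holds with a concentration-independent log-width, the
#' SDFs depend on size only through \eqn{s/s_c} with
#' \eqn{s_c \propto |\tilde\rho|^{-\phi}}; multiplying every size by
#' \eqn{|\tilde\rho|^{\phi}} should therefore superpose all
#' concentrations. The function rescales each (replicate-pooled)
#' concentration, computes all pairwise sup-distances between the
#' rescaled empirical SDFs, and reports per concentration the largest
#' distance to any other concentration.
#'
#' @param series a [concentration_series] with >= 2 concentrations.
#' @param rho_c critical concentration, above every concentration present.
#' @param phi rescaling exponent (default 1, the fitted value for the
#'   droplet data this analysis was developed on).
#' @return A `collapse_result`; `max_distance` is the largest pairwise
#'   distance.
#' @export
collapse_rho_rescale <- function(series, rho_c, phi = 1) {
  stopifnot(inherits(series, "concentration_series"))
  conc <- concentrations(series)
  if (length(conc) < 2L)
    stop("need >= 2 concentrations to assess collapse", call. = FALSE)
  curves <- lapply(conc, function(rho) {
    tab <- pool_tables(tables_at(series, rho))
    scaled <- droplet_table(tab$size * log_distance(rho, rho_c)^phi,
                            tab$count, concentration = rho,
                            replicate = tab$replicate)
    empirical_sdf(scaled)
  })
  n <- length(conc)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    d[i, j] <- d[j, i] <- sdf_sup_distance(curves[[i]], curves[[j]])
  }
  per <- data.frame(concentration = conc,
                    distance = apply(d, 1L, max))
  new_collapse_result("rho_rescale", per,
                      sprintf("pairwise rescaled SDFs, s * |rho_tilde|^%g",
                              phi))
}

#' Stationarity of the droplet size distribution over time
#'
#' Below the critical concentration the size distribution is expected to
#' stop evolving after an initial transient, although individual droplets
#' keep forming and dissolving. Each time point's empirical SDF is
#' compared (sup distance) with a reference time point, by default the
#' first measurement at or after 5 minutes.
#'
#' @param tables_over_time list of `list(time =, table =)` entries, as
#'   returned by [read_droplet_timetable()].
#' @param transient_min reference selection: first time point at or after
#'   this many minutes (falls back to the first time point).
#' @return `data.frame` with `time`, `distance` (vs the reference) and
#'   `reference` flag; empty with fewer than two time points.
#' @export
stationarity_check <- function(tables_over_time, transient_min = 5) {
  empty <- data.frame(time = numeric(), distance = numeric(),
                      reference = logical())
  if (length(tables_over_time) < 2L) return(empty)
  times <- vapply(tables_over_time, `[[`, numeric(1), "time")
  ord <- order(times)
  times <- times[ord]
  curves <- lapply(tables_over_time[ord],
                   function(e) empirical_sdf(e$table))
  ref <- which(times >= transient_min)[1L]
  if (is.na(ref)) ref <- 1L
  data.frame(
    time = times,
    distance = vapply(curves, sdf_sup_distance, numeric(1), curves[[ref]]),
    reference = seq_along(times) == ref)
}

#' Is the fitted log-width flat in concentration?
#'
#' Regresses the per-concentration log-normal width estimates on
#' concentration with inverse-variance weights and reports the slope, its
#' error and the t statistic. Scale invariance of the log-normal form
#' requires sigma to be independent of concentration, i.e. |t| small.
#'
#' @param series a [concentration_series].
#' @param variance_mode see [fit_lognormal()].
#' @return List with `slope`, `slope_err`, `t`, and the per-concentration
#'   fit table.
#' @export
sigma_flatness <- function(series, variance_mode = c("sample", "population")) {
  fits <- fit_lognormal_series(series, match.arg(variance_mode))
  wf <- weighted_linear_fit(fits$concentration, fits$sigma,
                            if (all(fits$sigma_err > 0)) fits$sigma_err)
  list(slope = wf$slope, slope_err = wf$slope_err,
       t = wf$slope / wf$slope_err, fits = fits)
}
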
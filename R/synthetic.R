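#' Specification of the synthetic droplet-size model
#'
#' Defines the generative model the analysis assumes: at concentration
#' `rho` below the critical concentration `rho_c`, droplet sizes are i.i.d.
#' log-normal with concentration-independent log-scale width `sigma` and a
#' characteristic size that diverges as
#' \deqn{s_c(\rho) = a\,|(\rho-\rho_c)/\rho_c|^{-\phi}.}
#' The log-normal median is \eqn{s_0 = s_c e^{-3\sigma^2/2}}, which makes
#' \eqn{s_c} exactly the ratio of the second to the first moment. Because
#' the generative law is exactly log-normal, the size-distribution
#' prefactor exponent alpha is identically 0.
#'
#' The defaults mirror the regime of the nanoparticle-tracking droplet
#' data: phi = 1, sigma = 1, rho_c = 5 uM, five concentrations spanning
#' 0.5–4 uM, three replicates of 5000 droplets each.
#'
#' @param rho_c critical concentration (uM).
#' @param a proportionality constant of the characteristic size (size
#'   units).
#' @param phi divergence exponent of the characteristic size (> 0).
#' @param sigma log-scale width of the log-normal (> 0; `sigma = 0` is
#'   allowed only for degenerate oracle checks).
#' @param concentrations concentrations to simulate, all strictly below
#'   `rho_c`.
#' @param n_droplets droplets per (concentration, replicate).
#' @param n_replicates replicates per concentration.
#' @param count_noise `"none"` (exact multiplicities) or `"poisson"`
#'   (per-bin counts replaced by Poisson draws, emulating abundance noise
#'   in nanoparticle tracking; requires `binning`).
#' @param binning optional list `list(n_bins =, spacing = "log"|"linear")`;
#'   when set, sampled sizes are histogrammed and represented by bin
#'   centres (geometric centres for log spacing).
#' @param seed integer master seed; every draw of [generate_series()] is a
#'   deterministic function of (seed, concentration index, replicate
#'   index).
#' @return An object of class `synthetic_model_spec`.
#' @seealso [generate_series()], [exact_moment_series()]
#' @export
synthetic_model_spec <- function(rho_c = 5, a = 1, phi = 1, sigma = 1,
                                 concentrations = c(0.5, 1, 2, 3, 4),
                                 n_droplets = 5000L, n_replicates = 3L,
                                 count_noise = c("none", "poisson"),
                                 binning = NULL, seed = 1L) {
  count_noise <- match.arg(count_noise)
  stopifnot(rho_c > 0, a > 0, phi > 0, sigma >= 0,
            n_droplets >= 1, n_replicates >= 1)
  concentrations <- as.numeric(concentrations)
  if (length(concentrations) == 0L || any(concentrations <= 0))
    stop("concentrations must be positive", call. = FALSE)
  if (any(concentrations >= rho_c))
    stop("all concentrations must be strictly below rho_c", call. = FALSE)
  if (!is.null(binning)) {
    if (!is.list(binning) || is.null(binning$n_bins))
      stop("binning must be list(n_bins =, spacing =)", call. = FALSE)
    if (binning$n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
    binning$spacing <- match.arg(binning$spacing %||% "log",
                                 c("log", "linear"))
  }
  if (count_noise == "poisson" && is.null(binning))
    stop("count_noise = 'poisson' requires binning", call. = FALSE)
  structure(list(rho_c = rho_c, a = a, phi = phi, sigma = sigma,
                 concentrations = sort(concentrations),
                 n_droplets = as.integer(n_droplets),
                 n_replicates = as.integer(n_replicates),
                 count_noise = count_noise, binning = binning,
                 seed = as.integer(seed)),
            class = "synthetic_model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Characteristic droplet size of the synthetic model
#'
#' \eqn{s_c = a\,|\tilde\rho|^{-\phi}} with
#' \eqn{\tilde\rho = (\rho-\rho_c)/\rho_c}; strictly increasing in `rho`
#' on (0, rho_c) and divergent at the critical concentration.
#'
#' @param spec a [synthetic_model_spec].
#' @param rho concentration (uM), strictly below `spec$rho_c`.
#' @return The characteristic size (size units).
#' @export
characteristic_size_model <- function(spec, rho) {
  if (any(rho <= 0) || any(rho >= spec$rho_c))
    stop("rho must lie in (0, rho_c): the model is defined only in the ",
         "subsaturated regime", call. = FALSE)
  spec$a * log_distance(rho, spec$rho_c)^(-spec$phi)
}

#' Draw droplet sizes at one concentration
#'
#' i.i.d. log-normal draws with median \eqn{s_0 = s_c e^{-3\sigma^2/2}}
#' and log-width sigma, where \eqn{s_c} comes from
#' [characteristic_size_model()]. Uses the current RNG state; for the
#' seeded replicate structure use [generate_series()].
#'
#' @param spec a [synthetic_model_spec].
#' @param rho concentration in (0, rho_c).
#' @param n number of droplets.
#' @return Numeric vector of `n` positive sizes.
#' @export
sample_droplets <- function(spec, rho, n) {
  stopifnot(n >= 1)
  s_c <- characteristic_size_model(spec, rho)
  meanlog <- log(s_c) - 1.5 * spec$sigma^2
  if (spec$sigma == 0) return(rep(exp(meanlog), n))
  stats::rlnorm(n, meanlog = meanlog, sdlog = spec$sigma)
}

# Deterministic per-table substream seed (kept < 2^31).
table_seed <- function(seed, conc_index, rep_index) {
  as.integer((as.double(seed) %% 1e6) * 1009 +
               conc_index * 7919 + rep_index) %% 2147483647L
}

#' Generate a synthetic concentration series
#'
#' One [droplet_table] per (concentration, replicate). Each table uses an
#' independent RNG substream derived deterministically from the spec seed
#' and the (concentration, replicate) indices, so a fixed spec reproduces
#' byte-identical output and per-table draws do not depend on how many
#' other tables are generated. With `binning`, sizes are histogrammed over
#' the sampled range and represented by bin centres; with
#' `count_noise = "poisson"` each bin count is replaced by a Poisson draw
#' with that mean (empty bins are dropped).
#'
#' @param spec a [synthetic_model_spec].
#' @return A [concentration_series] with `rho_c` recorded.
#' @examples
#' series <- generate_series(synthetic_model_spec(n_droplets = 200))
#' series
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "synthetic_model_spec"))
  tables <- list()
  for (ci in seq_along(spec$concentrations)) {
    rho <- spec$concentrations[ci]
    for (ri in seq_len(spec$n_replicates)) {
      tables[[length(tables) + 1L]] <-
        local_seed(table_seed(spec$seed, ci, ri), {
          sizes <- sample_droplets(spec, rho, spec$n_droplets)
          make_table_from_sizes(spec, sizes, rho, ri)
        })
    }
  }
  concentration_series(tables, rho_c = spec$rho_c)
}

# Evaluate expr with a temporary RNG seed, restoring the caller's state.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

make_table_from_sizes <- function(spec, sizes, rho, replicate) {
  if (is.null(spec$binning))
    return(droplet_table(sizes, concentration = rho, replicate = replicate,
                         protein = "synthetic"))
  nb <- spec$binning$n_bins
  if (spec$binning$spacing == "log") {
    edges <- exp(seq(log(min(sizes)), log(max(sizes)), length.out = nb + 1L))
    centres <- sqrt(edges[-1L] * edges[-(nb + 1L)])
  } else {
    edges <- seq(min(sizes), max(sizes), length.out = nb + 1L)
    centres <- (edges[-1L] + edges[-(nb + 1L)]) / 2
  }
  counts <- tabulate(findInterval(sizes, edges, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = nb)
  if (spec$count_noise == "poisson")
    counts <- stats::rpois(nb, counts)
  keep <- counts >= 1
  droplet_table(centres[keep], counts[keep], concentration = rho,
                replicate = replicate, protein = "synthetic")
}

#' Analytic moments of the synthetic model
#'
#' Noise-free moments \eqn{\langle s^k\rangle = s_c^k e^{\sigma^2 k(k-3)/2}}
#' for every concentration of the spec, packaged as [moment_set] objects
#' with zero replicate error. These are the deterministic oracle for all
#' estimator tests: fed to [estimate_phi()] or the critical-point
#' estimators they must recover the generative parameters exactly.
#'
#' @param spec a [synthetic_model_spec].
#' @param k_grid moment orders.
#' @return List of `moment_set` objects, one per concentration.
#' @export
exact_moment_series <- function(spec, k_grid) {
  stopifnot(inherits(spec, "synthetic_model_spec"))
  k_grid <- sort(unique(as.numeric(k_grid)))
  lapply(spec$concentrations, function(rho) {
    s_c <- characteristic_size_model(spec, rho)
    mom <- lognormal_moment(s_c, spec$sigma, k_grid)
    new_moment_set(concentration = rho, k = k_grid, mean = mom,
                   err = rep(0, length(k_grid)), n_replicates = 1L,
                   replicate_moments = matrix(mom, nrow = 1L,
                                              dimnames = list(NULL, k_grid)))
  })
}
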
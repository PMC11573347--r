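#' Droplet size table for one concentration and replicate
#'
#' The universal input of the package: the droplet sizes observed in one
#' replicate measurement at one protein concentration. Sizes may be raw
#' per-droplet values (`count` all 1, e.g. segmented droplet areas from
#' microscopy) or binned abundances (a size value with a multiplicity, as
#' produced by nanoparticle tracking analysis). All statistics in the
#' package treat `count` as an exact multiplicity, so a raw table and its
#' binned equivalent are interchangeable.
#'
#' @param size numeric vector of positive droplet sizes (arbitrary units:
#'   fluorescence intensity, area, volume, ...).
#' @param count positive integer multiplicities, recycled to `length(size)`;
#'   defaults to 1 (raw dialect).
#' @param concentration positive protein concentration in uM.
#' @param replicate integer replicate id (>= 1).
#' @param protein optional label for the protein measured.
#' @param size_kind what the size values measure; units are metadata only —
#'   every estimator in the package is covariant under a global rescaling of
#'   sizes, so no unit conversion is ever applied.
#' @return An object of class `droplet_table`.
#' @examples
#' tab <- droplet_table(c(1, 2, 4), concentration = 1, replicate = 1)
#' size_moment(tab, 1)
#' @export
droplet_table <- function(size, count = 1, concentration, replicate = 1L,
                          protein = "protein",
                          size_kind = c("arbitrary", "intensity", "area",
                                        "volume", "length")) {
  size_kind <- match.arg(size_kind)
  size <- as.numeric(size)
  count <- rep_len(as.numeric(count), length(size))
  if (length(size) == 0L)
    stop("droplet_table: 'size' must be non-empty", call. = FALSE)
  if (any(!is.finite(size)) || any(size <= 0))
    stop("droplet_table: all sizes must be finite and > 0", call. = FALSE)
  if (any(!is.finite(count)) || any(count < 1) || any(count != round(count)))
    stop("droplet_table: all counts must be integers >= 1", call. = FALSE)
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      !is.finite(concentration) || concentration <= 0)
    stop("droplet_table: 'concentration' must be a single positive number",
         call. = FALSE)
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L)
    stop("droplet_table: 'replicate' must be an integer >= 1", call. = FALSE)
  ord <- order(size)
  structure(
    list(protein = as.character(protein),
         concentration = as.numeric(concentration),
         replicate = replicate,
         size = size[ord],
         count = count[ord],
         size_kind = size_kind),
    class = "droplet_table")
}

#' @export
print.droplet_table <- function(x, ...) {
  cat(sprintf(
    "<droplet_table> %s at %g uM, replicate %d: %d distinct sizes, %g droplets (%s)\n",
    x$protein, x$concentration, x$replicate, length(x$size), sum(x$count),
    x$size_kind))
  invisible(x)
}

#' @export
as.data.frame.droplet_table <- function(x, ...) {
  data.frame(concentration_uM = x$concentration, replicate = x$replicate,
             size = x$size, count = x$count)
}

n_droplets <- function(table) sum(table$count)

#' Concentration series of droplet tables
#'
#' Bundles droplet tables measured at two or more protein concentrations —
#' all strictly below the critical concentration `rho_c` when it is known —
#' into the object consumed by the exponent and critical-point estimators.
#'
#' @param tables list of [droplet_table] objects spanning at least two
#'   distinct concentrations.
#' @param rho_c optional known critical concentration (uM). When set, every
#'   table must lie strictly below it: the scaling analysis is defined only
#'   in the subsaturated regime.
#' @param excluded concentrations (uM) to drop from all fits, e.g. the
#'   lowest measured concentration, which sits furthest from the critical
#'   point and outside the scaling regime.
#' @return An object of class `concentration_series`.
#' @seealso [generate_series()], [read_droplet_table()], [droplet_scaling()]
#' @export
concentration_series <- function(tables, rho_c = NULL, excluded = numeric()) {
  if (!is.list(tables) || length(tables) == 0L ||
      !all(vapply(tables, inherits, logical(1), "droplet_table")))
    stop("concentration_series: 'tables' must be a non-empty list of droplet_table",
         call. = FALSE)
  conc <- vapply(tables, `[[`, numeric(1), "concentration")
  if (!is.null(rho_c)) {
    if (!is.numeric(rho_c) || length(rho_c) != 1L || rho_c <= 0)
      stop("concentration_series: 'rho_c' must be a single positive number",
           call. = FALSE)
    if (any(conc >= rho_c))
      stop("concentration_series: all concentrations must be strictly below rho_c ",
           "(subsaturated regime)", call. = FALSE)
  }
  kinds <- unique(vapply(tables, `[[`, character(1), "size_kind"))
  if (length(kinds) > 1L)
    stop("concentration_series: tables mix size kinds: ",
         paste(kinds, collapse = ", "), call. = FALSE)
  # ragged replicate structure is allowed but flagged
  reps_by_conc <- lapply(split(
    vapply(tables, `[[`, integer(1), "replicate"), conc), sort)
  ragged <- length(unique(lapply(reps_by_conc, identity))) > 1L
  ord <- order(conc, vapply(tables, `[[`, integer(1), "replicate"))
  structure(
    list(tables = tables[ord], rho_c = rho_c,
         excluded = as.numeric(excluded), ragged_replicates = ragged),
    class = "concentration_series")
}

#' @export
print.concentration_series <- function(x, ...) {
  conc <- concentrations(x)
  cat(sprintf("<concentration_series> %d tables at %d concentrations (%s uM)\n",
              length(x$tables), length(conc),
              paste(format(conc), collapse = ", ")))
  if (!is.null(x$rho_c)) cat(sprintf("  rho_c = %g uM\n", x$rho_c))
  if (length(x$excluded))
    cat("  excluded:", paste(x$excluded, collapse = ", "), "uM\n")
  invisible(x)
}

#' @export
as.data.frame.concentration_series <- function(x, ...) {
  do.call(rbind, lapply(x$tables, as.data.frame))
}

#' Distinct concentrations of a series
#'
#' @param series a [concentration_series].
#' @param use_exclusions drop concentrations listed in `series$excluded`?
#' @return Sorted numeric vector of concentrations (uM).
#' @export
concentrations <- function(series, use_exclusions = FALSE) {
  conc <- sort(unique(vapply(series$tables, `[[`, numeric(1), "concentration")))
  if (use_exclusions) conc <- setdiff(conc, series$excluded)
  conc
}

# Tables at one concentration.
tables_at <- function(series, concentration) {
  keep <- vapply(series$tables, function(t) t$concentration == concentration,
                 logical(1))
  series$tables[keep]
}

# Merge replicate tables at one concentration into a single table
# (multiset union; replicate id of the first table is kept).
pool_tables <- function(tables) {
  stopifnot(length(tables) >= 1L)
  droplet_table(size = unlist(lapply(tables, `[[`, "size")),
                count = unlist(lapply(tables, `[[`, "count")),
                concentration = tables[[1L]]$concentration,
                replicate = tables[[1L]]$replicate,
                protein = tables[[1L]]$protein,
                size_kind = tables[[1L]]$size_kind)
}

# Apply exclusions (argument overrides the series field when non-NULL).
apply_exclusions <- function(series, exclusions = NULL) {
  excl <- if (is.null(exclusions)) series$excluded else as.numeric(exclusions)
  if (length(excl) == 0L) return(series)
  keep <- vapply(series$tables,
                 function(t) !(t$concentration %in% excl), logical(1))
  if (!any(keep))
    stop("all concentrations excluded", call. = FALSE)
  series$tables <- series$tables[keep]
  series$excluded <- excl
  series
}

#' Analysis configuration
#'
#' Collects the tunable choices of the full pipeline in one validated
#' object, mirroring the flat key/value configuration file accepted by
#' [read_analysis_config()].
#'
#' @param k_grid positive moment orders used for the moment-ratio and
#'   moment-intercept fits. Two named presets are available via
#'   [k_grid_preset()].
#' @param phi_fixed exponent used by the ratio-intercept critical-point
#'   estimator (the scaling fits of the source data support phi = 1).
#' @param exclusions concentrations (uM) dropped from all regressions.
#' @param seed integer seed for any simulation performed with this config.
#' @param method critical-point estimator: `"moment_intercept"` fits
#'   moments^(-1/k) against concentration, `"ratio_intercept"` fits
#'   (moment_k/moment_1)^(-1/(k-1)).
#' @param pooling pool critical-point estimates across moment orders
#'   (`"k"`, on replicate-averaged moments) or across replicates
#'   (`"replicate"`).
#' @param variance_mode `"sample"` (n-1 denominator) or `"population"` (n)
#'   for the log-size standard deviation in [fit_lognormal()].
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(k_grid = k_grid_preset("fus"),
                            phi_fixed = 1,
                            exclusions = numeric(),
                            seed = 1L,
                            method = c("moment_intercept", "ratio_intercept"),
                            pooling = c("k", "replicate"),
                            variance_mode = c("sample", "population")) {
  method <- match.arg(method)
  pooling <- match.arg(pooling)
  variance_mode <- match.arg(variance_mode)
  k_grid <- as.numeric(k_grid)
  if (length(k_grid) == 0L || any(k_grid <= 0))
    stop("analysis_config: k_grid values must be > 0", call. = FALSE)
  if (method == "ratio_intercept" && any(k_grid == 1))
    stop("analysis_config: ratio_intercept requires all k != 1", call. = FALSE)
  structure(list(k_grid = k_grid, phi_fixed = phi_fixed,
                 exclusions = as.numeric(exclusions), seed = as.integer(seed),
                 method = method, pooling = pooling,
                 variance_mode = variance_mode),
            class = "analysis_config")
}

#' Named moment-order grids
#'
#' `"fus"` is the grid used for the nanoparticle-tracking droplet data
#' (k = 0.5, 1, 1.5, 2); `"asyn"` the grid used for the imaged droplet
#' areas (k = 0.25, 0.75, 1.25, 1.75), which avoids k = 1 and so also suits
#' the ratio-intercept estimator.
#'
#' @param name preset name.
#' @return Numeric vector of moment orders.
#' @export
k_grid_preset <- function(name = c("fus", "asyn")) {
  switch(match.arg(name),
         fus  = c(0.5, 1, 1.5, 2),
         asyn = c(0.25, 0.75, 1.25, 1.75))
}
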
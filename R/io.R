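#' Read a droplet size table from CSV
#'
#' The canonical on-disk format is a UTF-8 CSV with a header row and columns
#' `concentration_uM`, `replicate`, `size` and — in the binned dialect —
#' `count`. The raw dialect (one row per droplet) omits `count`, which then
#' defaults to 1. Bare column names `concentration` and `conc` are accepted
#' as synonyms for `concentration_uM`. Decimal points and scientific
#' notation are parsed; parsing does not depend on the locale.
#'
#' @param path path to a CSV file.
#' @param dialect `"raw"` (per-droplet rows) or `"binned"` (size/abundance
#'   rows, as from nanoparticle tracking analysis).
#' @param rho_c optional critical concentration recorded on the series.
#' @param protein,size_kind metadata applied to every table read.
#' @return A [concentration_series] with one [droplet_table] per
#'   (concentration, replicate) pair present in the file.
#' @export
read_droplet_table <- function(path, dialect = c("raw", "binned"),
                               rho_c = NULL, protein = "protein",
                               size_kind = "arbitrary") {
  dialect <- match.arg(dialect)
  df <- read_table_csv(path, need_count = dialect == "binned")
  build_series_from_df(df, rho_c = rho_c, protein = protein,
                       size_kind = size_kind)
}

# Shared CSV reader + schema/row validation.
read_table_csv <- function(path, need_count, extra_cols = character()) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        stop("empty input file: ", path, call. = FALSE)
      stop(e)
    })
  if (nrow(df) == 0L && ncol(df) <= 1L)
    stop("empty input file: ", path, call. = FALSE)
  names(df)[names(df) %in% c("concentration", "conc")] <- "concentration_uM"
  required <- c("concentration_uM", "replicate", "size",
                if (need_count) "count", extra_cols)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L)
    stop("empty input file (header only): ", path, call. = FALSE)
  if (!"count" %in% names(df)) df$count <- 1
  for (col in c("concentration_uM", "size", "count"))
    df[[col]] <- as.numeric(df[[col]])
  df$replicate <- as.integer(df$replicate)
  bad <- which(!is.finite(df$size) | df$size <= 0)
  if (length(bad))
    stop("non-positive or non-numeric size at row ", bad[1L] + 1L,
         " (counting the header)", call. = FALSE)
  bad <- which(!is.finite(df$count) | df$count < 1)
  if (length(bad))
    stop("non-positive or non-numeric count at row ", bad[1L] + 1L,
         " (counting the header)", call. = FALSE)
  df
}

build_series_from_df <- function(df, rho_c, protein, size_kind) {
  key <- interaction(df$concentration_uM, df$replicate, drop = TRUE)
  tables <- lapply(split(df, key), function(g)
    droplet_table(size = g$size, count = g$count,
                  concentration = g$concentration_uM[1L],
                  replicate = g$replicate[1L],
                  protein = protein, size_kind = size_kind))
  concentration_series(unname(tables), rho_c = rho_c)
}

#' Write a concentration series to CSV
#'
#' Rows are ordered by (concentration, replicate, size) so output is
#' deterministic; the file rereads with [read_droplet_table()] to a series
#' equal field-for-field. Writing a binned table in the raw dialect expands
#' each row to `count` identical rows, which leaves every downstream
#' statistic unchanged.
#'
#' @param series a [concentration_series].
#' @param path output path.
#' @param dialect `"raw"` or `"binned"` (see [read_droplet_table()]).
#' @return Invisibly, `path`.
#' @export
write_droplet_table <- function(series, path, dialect = c("raw", "binned")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(series, "concentration_series"))
  df <- as.data.frame(series)
  df <- df[order(df$concentration_uM, df$replicate, df$size), , drop = FALSE]
  if (dialect == "raw") {
    df <- df[rep(seq_len(nrow(df)), times = df$count), , drop = FALSE]
    df$count <- NULL
  }
  ok <- tryCatch(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
                 error = function(e)
                   stop("cannot write to ", path, ": ", conditionMessage(e),
                        call. = FALSE))
  invisible(path)
}

#' Read a droplet time series for stationarity analysis
#'
#' Same schema as [read_droplet_table()] plus a `time_min` column; each
#' (time, replicate) group becomes one table. Used with
#' [stationarity_check()].
#'
#' @param path CSV path.
#' @param concentration concentration (uM) at which the time series was
#'   recorded (a single value; the file does not need a concentration
#'   column if this is given).
#' @param dialect `"raw"` or `"binned"`.
#' @return List with elements `time` (minutes) and `table`
#'   ([droplet_table]), ordered by time.
#' @export
read_droplet_timetable <- function(path, concentration = NULL,
                                   dialect = c("raw", "binned")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  if (!"time_min" %in% names(df))
    stop("missing column(s): time_min", call. = FALSE)
  if (!"concentration_uM" %in% names(df)) {
    if (is.null(concentration))
      stop("no concentration_uM column and no 'concentration' argument",
           call. = FALSE)
    df$concentration_uM <- concentration
  }
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  if (!"count" %in% names(df)) df$count <- 1
  groups <- split(df, df$time_min)
  times <- as.numeric(names(groups))
  out <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    list(time = times[i],
         table = droplet_table(size = as.numeric(g$size),
                               count = as.numeric(g$count),
                               concentration = g$concentration_uM[1L],
                               replicate = as.integer(g$replicate[1L])))
  })
  out[order(times)]
}

#' Read an analysis configuration file
#'
#' Flat YAML key/value file whose keys mirror the arguments of
#' [analysis_config()]; unknown keys are an error so typos do not silently
#' fall back to defaults.
#'
#' @param path YAML file path.
#' @return An [analysis_config] object.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(analysis_config, vals)
}

#' Write a machine-readable result report
#'
#' Serializes a fitted result (an exponent fit, a critical-point estimate,
#' a collapse result, or a full [droplet_scaling] fit) to JSON at full
#' numeric precision, together with the package version. Reports reread
#' with [jsonlite::read_json()] reproduce every fitted number exactly.
#'
#' @param result object to report.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(result, path) {
  payload <- report_payload(result)
  check_populated(payload, deparse(substitute(result)))
  payload$software <- paste0("dropletscaling ",
                             as.character(utils::packageVersion("dropletscaling")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}

check_populated <- function(x, what) {
  bad <- character()
  walk <- function(v, name) {
    if (is.list(v)) {
      nm <- names(v) %||% as.character(seq_along(v))
      for (i in seq_along(v)) walk(v[[i]], paste0(name, "$", nm[i]))
    } else if (is.numeric(v) && any(!is.finite(v))) {
      # NA in an optional 'replicate' column of per-fit tables is legitimate
      if (!grepl("replicate", name)) bad <<- c(bad, name)
    }
  }
  walk(x, what)
  if (length(bad))
    stop("cannot report partially populated result: ",
         paste(bad, collapse = ", "), " not finite", call. = FALSE)
  invisible(TRUE)
}

report_payload <- function(result) UseMethod("report_payload")

#' @export
report_payload.default <- function(result) {
  if (is.list(result)) return(lapply(unclass(result), report_payload_leaf))
  report_payload_leaf(result)
}

report_payload_leaf <- function(x) {
  if (inherits(x, "wls_fit")) return(unclass(x)[c(
    "slope", "intercept", "slope_err", "intercept_err", "r_squared",
    "n_points")])
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, report_payload_leaf))
  x
}

#' @export
report_payload.exponent_fit <- function(result) {
  list(type = "exponent_fit",
       phi = result$phi, phi_err = result$phi_err,
       m = result$m, m_err = result$m_err,
       alpha = result$alpha, phi_used = result$phi_used,
       rho_c_used = result$rho_c_used,
       k_grid = result$k_grid, exclusions = result$exclusions,
       per_k_slopes = vapply(result$per_k, `[[`, numeric(1), "slope"),
       per_k_slope_errs = vapply(result$per_k, `[[`, numeric(1), "slope_err"),
       per_k = lapply(result$per_k, report_payload_leaf))
}

#' @export
report_payload.critical_point_estimate <- function(result) {
  list(type = "critical_point_estimate", method = result$method,
       rho_c = result$rho_c, rho_c_err = result$rho_c_err,
       pooling = result$pooling, k_grid = result$k_grid,
       phi_fixed = result$phi_fixed, per_fit = result$per_fit)
}

#' @export
report_payload.collapse_result <- function(result) {
  list(type = "collapse_result", mode = result$mode,
       reference = result$reference,
       max_distance = result$max_distance,
       per_concentration = result$per_concentration)
}

#' @export
report_payload.droplet_scaling <- function(result) {
  list(type = "droplet_scaling",
       rho_c = result$rho_c, rho_c_err = result$rho_c_err,
       critical_point = if (!is.null(result$critical_point))
         report_payload(result$critical_point),
       exponents = report_payload(result$exponents),
       lognormal = result$lognormal,
       k_grid = result$k_grid, exclusions = result$exclusions)
}
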
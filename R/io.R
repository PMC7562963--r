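# Readers and writers for the package's delimited text formats, and the
# run-configuration loader.

#' Construct a forcing series
#'
#' A forcing series is a data frame with one row per time step and the
#' columns `step`, `R` (global + supplementary radiation, J cm^-2),
#' `T_tube` (heating-pipe temperature, deg C), `T_gh` (greenhouse air
#' temperature, deg C) and one or more `irrigation_*` columns (applied
#' water depth per step, mm), one per irrigation strategy.
#'
#' @param df Data frame with the columns above.
#' @param steps_per_day Number of forcing steps per day (default 24,
#'   i.e. hourly forcing).
#' @return A `forcing_series` (a validated data frame carrying the
#'   `steps_per_day` and strategy-column attributes).
#' @export
forcing_series <- function(df, steps_per_day = 24L) {
  need <- c("step", "R", "T_tube", "T_gh")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("forcing is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  strategies <- grep("^irrigation", names(df), value = TRUE)
  if (length(strategies) == 0L) {
    stop("forcing has no irrigation_* strategy column", call. = FALSE)
  }
  if (nrow(df) == 0L) stop("forcing series is empty", call. = FALSE)
  num_cols <- c("R", "T_tube", "T_gh", strategies)
  for (cl in num_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cl]]))))
    if (length(bad)) {
      stop("non-numeric or missing values in column ", cl, " at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    df[[cl]] <- as.numeric(df[[cl]])
  }
  bad <- which(df$R < 0)
  if (length(bad)) {
    stop("negative radiation at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  for (cl in strategies) {
    bad <- which(df[[cl]] < 0)
    if (length(bad)) {
      stop("negative irrigation in ", cl, " at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
  }
  structure(df, steps_per_day = as.integer(steps_per_day),
            strategies = strategies,
            class = c("forcing_series", "data.frame"))
}

#' Read a forcing file
#'
#' Tab-delimited text with a header row and the columns documented in
#' [forcing_series].  A comment line `# steps_per_day=N` records the
#' temporal resolution (24 assumed when absent).  Missing values are
#' rejected, never imputed.
#'
#' @param path Path to the forcing file.
#' @return A [forcing_series].
#' @export
read_forcing <- function(path) {
  if (!file.exists(path)) stop("forcing file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  spd <- 24L
  if (grepl("^#\\s*steps_per_day\\s*=", first)) {
    spd <- as.integer(sub("^#\\s*steps_per_day\\s*=\\s*", "", first))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  forcing_series(df, steps_per_day = spd)
}

#' Write a forcing file
#'
#' @param forcing A [forcing_series].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_forcing <- function(forcing, path) {
  stopifnot(inherits(forcing, "forcing_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# steps_per_day=%d", attr(forcing, "steps_per_day")), con)
  df <- as.data.frame(forcing)
  for (cl in setdiff(names(df), "step")) df[[cl]] <- sprintf("%.17g", df[[cl]])
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.SUMMARY_COLS <- c("strategy", "total_irrigation", "risk_mean", "risk_std",
                   "drainage_mean", "drainage_std", "et_mean", "et_std")

#' Write an ensemble summary table
#'
#' One row per irrigation strategy with mean/std pairs for the crop
#' stress ratio ("risk"), cumulative drainage (mm) and cumulative
#' evapotranspiration (mm) — the machine-readable form of the classic
#' drainage/risk/ET trade-off table.
#'
#' @param summary An `ensemble_summary` from [run_ensemble], or a data
#'   frame with the same `$summary` columns.
#' @param path Output path (tab-delimited text).
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  df <- if (inherits(summary, "ensemble_summary")) summary$summary else summary
  if (!is.data.frame(df) || nrow(df) == 0L) {
    stop("refusing to write an empty summary", call. = FALSE)
  }
  miss <- setdiff(.SUMMARY_COLS, names(df))
  if (length(miss)) {
    stop("summary is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, .SUMMARY_COLS]
  for (cl in setdiff(.SUMMARY_COLS, "strategy")) {
    df[[cl]] <- sprintf("%.17g", df[[cl]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ensemble summary table written by [write_summary]
#'
#' @param path Path to the summary file.
#' @return A data frame with the summary columns.
#' @export
read_summary <- function(path) {
  if (!file.exists(path)) stop("summary file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  miss <- setdiff(.SUMMARY_COLS, names(df))
  if (length(miss)) {
    stop("not a summary file; missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' Load and validate a run configuration
#'
#' A single YAML file describing a complete run: paths to the forcing and
#' soil-catalogue files (relative paths resolve against the config file's
#' directory), the solver grid, the initial condition, the crop/ET
#' parameters, the uncertainty switches and the stress threshold.  All
#' referenced files must exist and parse before any simulation starts.
#'
#' @param path Path to the YAML configuration.
#' @return A `run_config` list with elements `forcing` (a
#'   [forcing_series]), `catalogue`, `solver`, `column`, `initial_h`,
#'   `et`, `uncertainty`, `stress` and `output`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base, p)

  for (key in c("forcing", "soil_catalogue", "et", "uncertainty", "stress")) {
    if (is.null(raw[[key]])) stop("config is missing key: ", key, call. = FALSE)
  }
  forcing <- read_forcing(resolve(raw$forcing))
  catalogue <- read_soil_catalogue(resolve(raw$soil_catalogue))

  sv <- raw$solver %||% list()
  column <- list(depth = sv$depth %||% 100, n_cells = sv$n_cells %||% 100,
                 root_depth = sv$root_depth %||% 30,
                 bottom = sv$bottom %||% "free")
  cfg <- solver_config(
    dt_init = sv$dt_init, dt_min = sv$dt_min %||% 1e-6,
    tol_h = sv$tol_h %||% 1e-4, max_iter = sv$max_iter %||% 50L,
    tol_mb = sv$tol_mb %||% 1e-3,
    monitor_cells = seq_len(sv$monitor_cells %||% 8L))

  et <- et_params(a = raw$et[["a"]], b = raw$et[["b"]],
                  L = raw$et[["L"]] %||% 1, Lmax = raw$et[["Lmax"]] %||% 1,
                  LAI = raw$et[["LAI"]] %||% 3,
                  full_grown = raw$et[["full_grown"]] %||% FALSE,
                  extinction = raw$et[["extinction"]] %||% 0.6)
  unc <- uncertainty_spec(
    et_uncertain = raw$uncertainty$et_uncertain %||% FALSE,
    soil_uncertain = raw$uncertainty$soil_uncertain %||% FALSE,
    soil_class = raw$uncertainty$soil_class %||% "sand",
    n_samples = raw$uncertainty$n_samples %||% 1L,
    seed = raw$uncertainty$seed %||% 1L)
  stress <- stress_config(
    threshold = raw$stress$threshold,
    monitored_cells = raw$stress$monitored_cells %||% 5:8)
  if (is.null(raw$initial$h)) {
    stop("config must state the initial condition (initial: h: <cm>)",
         call. = FALSE)
  }

  structure(list(forcing = forcing, catalogue = catalogue, column = column,
                 solver = cfg, initial_h = raw$initial$h, et = et,
                 uncertainty = unc, stress = stress,
                 output = resolve(raw$output %||% ".")),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
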
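# Synthetic fixture generation: plausible greenhouse forcing series, an
# irrigation-strategy sweep and a representative sand/clay soil
# catalogue, so the whole pipeline runs and tests offline.
#
# All numeric defaults here are illustrative placeholders for greenhouse
# data, not measurements: a diurnal radiation sinusoid, a mildly varying
# indoor air temperature, heating pipes active at night, and crop
# factors chosen so a default day yields a few millimetres of ET.

#' Specification for synthetic greenhouse fixtures
#'
#' @param n_days Number of simulated days (`>= 1`).
#' @param steps_per_day Forcing steps per day (default 24, hourly).
#' @param radiation_peak Midday peak of the diurnal radiation sinusoid
#'   (J cm^-2 per step); radiation is exactly zero outside 06:00-18:00.
#' @param t_gh Mean greenhouse air temperature (deg C).
#' @param t_tube_boost Heating-pipe temperature excess over the air
#'   during heating hours (deg C).
#' @param heating_hours Hours of day (0-23) in which the pipes are hot.
#' @param irrigation_daily Daily irrigation totals (mm d^-1), one per
#'   strategy; the default is an 8-strategy increasing sweep.
#' @param pulse_hours Hours of day over which each day's irrigation is
#'   spread evenly.
#' @param noise_radiation,noise_temperature Gaussian noise s.d. on the
#'   daytime radiation (J cm^-2) and on the air temperature (deg C).
#' @param seed RNG seed; fixtures are bit-identical per seed.
#'
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_days = 10L, steps_per_day = 24L,
                         radiation_peak = 150, t_gh = 20, t_tube_boost = 25,
                         heating_hours = c(0:5, 18:23),
                         irrigation_daily = seq(2, 16, by = 2),
                         pulse_hours = 8:17,
                         noise_radiation = 5, noise_temperature = 0.3,
                         seed = 42L) {
  if (n_days < 1L) stop("n_days must be >= 1", call. = FALSE)
  if (steps_per_day < 1L) stop("steps_per_day must be >= 1", call. = FALSE)
  if (radiation_peak < 0 || any(irrigation_daily < 0)) {
    stop("radiation and irrigation must be non-negative", call. = FALSE)
  }
  structure(list(n_days = as.integer(n_days),
                 steps_per_day = as.integer(steps_per_day),
                 radiation_peak = radiation_peak, t_gh = t_gh,
                 t_tube_boost = t_tube_boost, heating_hours = heating_hours,
                 irrigation_daily = irrigation_daily,
                 pulse_hours = pulse_hours,
                 noise_radiation = noise_radiation,
                 noise_temperature = noise_temperature,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic greenhouse forcing series
#'
#' Radiation follows a half-sine between 06:00 and 18:00 with additive
#' daytime noise (clipped at zero; night steps are exactly zero).  The
#' air temperature fluctuates mildly around its mean; the heating-pipe
#' temperature equals the air temperature plus `t_tube_boost` during
#' heating hours.  Each strategy's daily irrigation total is spread
#' evenly over the pulse hours, so daily column sums match the specified
#' totals exactly.
#'
#' @param spec A [fixture_spec].
#' @param path Optional output path; when given, the series is also
#'   written with [write_forcing].
#' @return A [forcing_series].
#' @export
make_forcing <- function(spec = fixture_spec(), path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_days * spec$steps_per_day
  hour <- (seq_len(n) - 1L) %% spec$steps_per_day * (24 / spec$steps_per_day)

  daylight <- hour >= 6 & hour < 18
  R <- numeric(n)
  R[daylight] <- spec$radiation_peak * sin(pi * (hour[daylight] - 6) / 12) +
    stats::rnorm(sum(daylight), 0, spec$noise_radiation)
  R <- pmax(R, 0)

  T_gh <- spec$t_gh + 1.5 * sin(2 * pi * (hour - 9) / 24) +
    stats::rnorm(n, 0, spec$noise_temperature)
  T_tube <- T_gh + ifelse(floor(hour) %in% spec$heating_hours,
                          spec$t_tube_boost, 0)

  df <- data.frame(step = seq_len(n), R = R, T_tube = T_tube, T_gh = T_gh)
  pulse <- floor(hour) %in% spec$pulse_hours
  pulses_per_day <- sum(floor(
    (seq_len(spec$steps_per_day) - 1L) * 24 / spec$steps_per_day
  ) %in% spec$pulse_hours)
  for (j in seq_along(spec$irrigation_daily)) {
    irr <- numeric(n)
    irr[pulse] <- spec$irrigation_daily[j] / pulses_per_day
    df[[sprintf("irrigation_%d", j)]] <- irr
  }

  fs <- forcing_series(df, steps_per_day = spec$steps_per_day)
  if (!is.null(path)) write_forcing(fs, path)
  fs
}

# Representative literature parameter sets for coarse (sand) and fine
# (clay) textures.  Illustrative values for testing, not site data.
.SOIL_LIBRARY <- list(
  sand = list(
    list("sand",       0.045, 0.43, 0.145, 2.68, 712.8),
    list("loamy_sand", 0.057, 0.41, 0.124, 2.28, 350.2),
    list("sandy_loam", 0.065, 0.41, 0.075, 1.89, 106.1)),
  clay = list(
    list("clay",       0.068, 0.38, 0.008, 1.09, 4.80),
    list("silty_clay", 0.070, 0.36, 0.005, 1.09, 0.48),
    list("clay_loam",  0.095, 0.41, 0.019, 1.31, 6.24)))

#' Generate a representative soil catalogue
#'
#' Three Van Genuchten-Mualem parameter sets per texture class, taken
#' from widely used literature compilations of soil hydraulic
#' properties.  They are illustrative stand-ins for a site-specific
#' catalogue: sands have high `Ks` and steep retention, clays low `Ks`
#' and gradual retention.
#'
#' @param class `"sand"`, `"clay"` or `"both"`.
#' @param path Optional output path; when given, the catalogue is also
#'   written with [write_soil_catalogue].
#' @return A `soil_catalogue` list of [soil_params].
#' @export
make_soil_catalogue <- function(class = c("both", "sand", "clay"),
                                path = NULL) {
  class <- match.arg(class)
  classes <- if (class == "both") c("sand", "clay") else class
  cat <- list()
  for (cl in classes) {
    for (e in .SOIL_LIBRARY[[cl]]) {
      cat[[e[[1]]]] <- soil_params(e[[1]], e[[2]], e[[3]], e[[4]], e[[5]],
                                   e[[6]], lam = 0.5, class = cl)
    }
  }
  cat <- structure(cat, class = "soil_catalogue")
  if (!is.null(path)) write_soil_catalogue(cat, path)
  cat
}

#' Write a complete ready-to-run fixture set
#'
#' Generates the forcing file, the soil catalogue and a YAML run
#' configuration wired to them, so `read_run_config()` on the returned
#' config path yields a runnable setup.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [fixture_spec].
#' @param n_samples,seed Monte Carlo settings written into the config.
#' @param threshold Stress threshold (cm) written into the config; the
#'   default -80 cm is an illustrative value for a coarse greenhouse
#'   substrate and should be replaced for real crops.
#' @return The path of the written config file, invisibly.
#' @export
make_fixtures <- function(dir, spec = fixture_spec(), n_samples = 20L,
                          seed = 1L, threshold = -80) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  make_forcing(spec, file.path(dir, "forcing.tsv"))
  make_soil_catalogue("both", file.path(dir, "soils.tsv"))
  cfg <- list(
    forcing = "forcing.tsv",
    soil_catalogue = "soils.tsv",
    solver = list(depth = 100, n_cells = 50, root_depth = 30,
                  bottom = "free", monitor_cells = 8),
    initial = list(h = -30),
    et = list(a = 0.002, b = 0.008, LAI = 3, full_grown = TRUE),
    uncertainty = list(et_uncertain = TRUE, soil_uncertain = TRUE,
                       soil_class = "sand", n_samples = n_samples,
                       seed = seed),
    stress = list(threshold = threshold, monitored_cells = 5:8),
    output = "results")
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}
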
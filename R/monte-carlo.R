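# Monte Carlo propagation of evapotranspiration and soil uncertainty
# through the soil-water simulator, per irrigation strategy.
#
# ET uncertainty is a bootstrap of the daily ET totals: each simulated
# day's demand is drawn with replacement from the pool of observed daily
# totals, then redistributed over that day's steps proportionally to the
# original within-day profile.  Soil uncertainty is a categorical draw
# over the soil-type catalogue of the active texture class.

#' Uncertainty switches for an ensemble run
#'
#' @param et_uncertain Resample daily evapotranspiration totals
#'   (bootstrap) for every Monte Carlo sample?
#' @param soil_uncertain Draw the soil type at random from the catalogue
#'   for every Monte Carlo sample?
#' @param soil_class Texture class of the active catalogue, `"sand"` or
#'   `"clay"`.
#' @param n_samples Number of Monte Carlo repeats per strategy (`>= 1`).
#'   With both switches off every sample is identical and the ensemble
#'   collapses to the deterministic run.
#' @param seed Root random seed; all per-sample draws derive from it
#'   deterministically.
#'
#' @return An object of class `uncertainty_spec`.
#' @export
uncertainty_spec <- function(et_uncertain = FALSE, soil_uncertain = FALSE,
                             soil_class = c("sand", "clay"), n_samples = 1L,
                             seed = 1L) {
  soil_class <- match.arg(soil_class)
  if (n_samples < 1L) stop("n_samples must be >= 1", call. = FALSE)
  structure(list(et_uncertain = isTRUE(et_uncertain),
                 soil_uncertain = isTRUE(soil_uncertain),
                 soil_class = soil_class,
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "uncertainty_spec")
}

#' Bootstrap-resample a daily evapotranspiration series
#'
#' Each output day is drawn independently, uniformly with replacement,
#' from the observed daily totals, using the current RNG state.
#'
#' @param daily_et Observed daily ET totals (mm d^-1), length `>= 1`.
#' @return A resampled series of the same length; every value occurs in
#'   the input.
#' @export
sample_et_series <- function(daily_et) {
  if (length(daily_et) == 0L) stop("empty daily ET pool", call. = FALSE)
  daily_et[sample.int(length(daily_et), length(daily_et), replace = TRUE)]
}

#' Draw one soil type from a catalogue
#'
#' Uniform categorical draw over the catalogue entries, using the current
#' RNG state.
#'
#' @param catalogue A non-empty list of [soil_params] objects.
#' @return One [soil_params] entry.
#' @export
sample_soil <- function(catalogue) {
  if (length(catalogue) == 0L) stop("empty soil catalogue", call. = FALSE)
  catalogue[[sample.int(length(catalogue), 1L)]]
}

# Rescale the per-step ET profile so each day sums to its resampled total,
# preserving the original within-day shape (uniform when a day was all-zero).
.rescale_daily_et <- function(ET_step, day_index, new_daily) {
  orig_daily <- as.numeric(tapply(ET_step, day_index, sum))
  out <- ET_step
  for (d in seq_along(orig_daily)) {
    idx <- which(day_index == d)
    if (orig_daily[d] > 0) {
      out[idx] <- ET_step[idx] * new_daily[d] / orig_daily[d]
    } else {
      out[idx] <- new_daily[d] / length(idx)
    }
  }
  out
}

#' Run a Monte Carlo ensemble over all irrigation strategies
#'
#' For every irrigation strategy in the forcing and every Monte Carlo
#' sample, draws the uncertain inputs (resampled daily ET and/or soil
#' type), simulates the soil column, and records cumulative drainage,
#' cumulative ET demand and the crop stress ratio.  Draws are made once
#' per sample and shared across strategies (common random numbers), so
#' strategy comparisons are paired.  The whole ensemble is reproducible
#' from `spec$seed`.
#'
#' @param forcing A [forcing_series].
#' @param catalogue A soil catalogue ([read_soil_catalogue]); entries
#'   tagged with `spec$soil_class` form the active pool (all entries if
#'   none is tagged).  In deterministic mode the first active entry is
#'   used.
#' @param et An [et_params] object.
#' @param stress A [stress_config].
#' @param spec An [uncertainty_spec].
#' @param column List of [soil_column] geometry arguments
#'   (`depth`, `n_cells`, `root_depth`, `bottom`).
#' @param cfg A [solver_config].
#' @param initial_h Initial uniform pressure head (cm) of the column.
#'
#' @return An object of class `ensemble_summary`: `$summary`, one row per
#'   strategy with `total_irrigation` (mm) and mean/std of the stress
#'   ratio, cumulative drainage (mm) and cumulative ET (mm); `$samples`,
#'   the per-(strategy, sample) raw values; and the run metadata.
#' @export
run_ensemble <- function(forcing, catalogue, et, stress, spec,
                         column = list(), cfg = solver_config(),
                         initial_h = -30) {
  stopifnot(inherits(forcing, "forcing_series"),
            inherits(spec, "uncertainty_spec"),
            inherits(stress, "stress_config"))
  strategies <- attr(forcing, "strategies")
  spd <- attr(forcing, "steps_per_day")
  n_steps <- nrow(forcing)
  day_index <- (seq_len(n_steps) - 1L) %/% spd + 1L

  tagged <- Filter(function(p) identical(p$class, spec$soil_class), catalogue)
  active <- if (length(tagged)) tagged else catalogue

  ET_base <- degraaf_et(forcing$R, forcing$T_tube, forcing$T_gh, et)
  daily_pool <- as.numeric(tapply(ET_base, day_index, sum))

  # one stream of per-sample seeds; sample k reuses its draws across
  # strategies (common random numbers)
  set.seed(spec$seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_samples)

  samples <- expand.grid(sample = seq_len(spec$n_samples),
                         strategy = seq_along(strategies))
  samples <- samples[order(samples$strategy, samples$sample), c(2, 1)]
  samples$soil <- NA_character_
  samples$risk <- NA_real_
  samples$drainage <- NA_real_
  samples$et <- NA_real_
  row.names(samples) <- NULL

  draws <- vector("list", spec$n_samples)
  for (k in seq_len(spec$n_samples)) {
    set.seed(sample_seeds[k])
    soil_k <- if (spec$soil_uncertain) sample_soil(active) else active[[1L]]
    ET_k <- if (spec$et_uncertain) {
      .rescale_daily_et(ET_base, day_index, sample_et_series(daily_pool))
    } else {
      ET_base
    }
    draws[[k]] <- list(soil = soil_k, ET = ET_k)
  }

  for (s in seq_along(strategies)) {
    for (k in seq_len(spec$n_samples)) {
      dk <- draws[[k]]
      col <- soil_column(dk$soil, depth = column$depth %||% 100,
                         n_cells = column$n_cells %||% 100,
                         root_depth = column$root_depth %||% 30,
                         bottom = column$bottom %||% "free")
      init <- column_state(col, h = initial_h)
      res <- tryCatch(
        simulate_column(col, init, forcing, et, cfg, strategy = s, ET = dk$ET),
        error = function(e) {
          stop(sprintf(
            "ensemble run failed (strategy %d, sample %d, seed %d): %s",
            s, k, sample_seeds[k], conditionMessage(e)), call. = FALSE)
        })
      i <- (s - 1L) * spec$n_samples + k
      samples$soil[i] <- dk$soil$name
      samples$risk[i] <- crop_stress_ratio(
        mean_root_zone_head(res$h_monitor, stress), stress$threshold)
      samples$drainage[i] <- res$cumulative$drainage * 10  # cm -> mm
      samples$et[i] <- sum(dk$ET)                          # mm
    }
  }

  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  agg <- function(f, v) as.numeric(tapply(samples[[v]], samples$strategy, f))
  summary <- data.frame(
    strategy = strategies,
    total_irrigation = vapply(strategies, function(s) sum(forcing[[s]]), 0),
    risk_mean = agg(mean, "risk"), risk_std = agg(sd0, "risk"),
    drainage_mean = agg(mean, "drainage"), drainage_std = agg(sd0, "drainage"),
    et_mean = agg(mean, "et"), et_std = agg(sd0, "et"),
    stringsAsFactors = FALSE)
  row.names(summary) <- NULL

  structure(list(summary = summary, samples = samples, spec = spec,
                 sample_seeds = sample_seeds),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary> %d strategies x %d samples (seed %d)\n",
              nrow(x$summary), x$spec$n_samples, x$spec$seed))
  df <- x$summary
  df[-1] <- lapply(df[-1], function(v) round(v, 3))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
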
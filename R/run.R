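# High-level drivers: run a configured ensemble (or a single
# deterministic simulation) and write its outputs.  These are the
# functions behind the command-line verbs in inst/cli/irrisim.R.

#' Run the full Monte Carlo ensemble described by a run configuration
#'
#' Executes [run_ensemble] with the forcing, catalogue, solver and
#' uncertainty settings of a [read_run_config] object and writes the
#' summary table (`summary.tsv`), the per-sample raw results
#' (`samples.tsv`) and, when there are at least two strategies, the
#' trade-off figure (`tradeoff.png`) into the configured output
#' directory.
#'
#' @param config A `run_config` from [read_run_config], or a path to a
#'   YAML configuration file.
#' @param out_dir Output directory override; defaults to the config's
#'   `output` entry.
#' @param quiet Suppress progress messages.
#' @return The `ensemble_summary`, invisibly.
#' @export
run_from_config <- function(config, out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- out_dir %||% config$output
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  spec <- config$uncertainty
  if (!quiet) {
    message(sprintf(
      "ensemble: %d strategies x %d samples (ET %s, soil %s [%s], seed %d)",
      length(attr(config$forcing, "strategies")), spec$n_samples,
      if (spec$et_uncertain) "uncertain" else "fixed",
      if (spec$soil_uncertain) "uncertain" else "fixed",
      spec$soil_class, spec$seed))
  }
  ens <- run_ensemble(config$forcing, config$catalogue, config$et,
                      config$stress, spec, column = config$column,
                      cfg = config$solver, initial_h = config$initial_h)
  write_summary(ens, file.path(out_dir, "summary.tsv"))
  utils::write.table(ens$samples, file.path(out_dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(ens$summary) >= 2L) {
    plot_tradeoff(ens, file.path(out_dir, "tradeoff.png"))
  }
  if (!quiet) message("wrote ", out_dir, "/{summary.tsv, samples.tsv}")
  invisible(ens)
}

#' Run a single deterministic simulation from a run configuration
#'
#' Uses the first catalogue entry of the configured soil class, the
#' unresampled ET series and one irrigation strategy; writes the per-step
#' ledger to `simulation.tsv` in the output directory.
#'
#' @inheritParams run_from_config
#' @param strategy Irrigation strategy index to simulate.
#' @return The `simulation_result`, invisibly.
#' @export
simulate_from_config <- function(config, strategy = 1L, out_dir = NULL,
                                 quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- out_dir %||% config$output
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  tagged <- Filter(function(p) identical(p$class, config$uncertainty$soil_class),
                   config$catalogue)
  soil <- if (length(tagged)) tagged[[1L]] else config$catalogue[[1L]]
  col <- soil_column(soil, depth = config$column$depth,
                     n_cells = config$column$n_cells,
                     root_depth = config$column$root_depth,
                     bottom = config$column$bottom)
  init <- column_state(col, h = config$initial_h)
  res <- simulate_column(col, init, config$forcing, config$et,
                         config$solver, strategy = strategy)
  out <- cbind(res$steps,
               stats::setNames(as.data.frame(res$h_monitor),
                               sprintf("h_cell_%d", config$solver$monitor_cells)))
  utils::write.table(out, file.path(out_dir, "simulation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!quiet) {
    message(sprintf("simulated strategy %d on %s: drainage %.2f mm, ET %.2f mm",
                    strategy, soil$name, res$cumulative$drainage * 10,
                    res$cumulative$et_demand * 10))
  }
  invisible(res)
}
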
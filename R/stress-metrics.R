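# Crop water-stress diagnostics from the monitored root-zone
# pressure-head trace.  Stress here is a *signal*, not an uptake
# reduction: the crop counts as stressed in any hour in which the mean
# root-zone pressure head falls below a threshold.

#' Stress-ratio configuration
#'
#' @param threshold Pressure head threshold (cm, `<= 0`) below which the
#'   crop is considered stressed.  There is no universal default: the
#'   value is crop- and substrate-specific and must be chosen by the user.
#' @param monitored_cells Indices *within the monitored-layer trace* that
#'   are averaged into the root-zone head (default `5:8`, the lower half
#'   of the default 8-cell first soil layer).
#'
#' @return An object of class `stress_config`.
#' @export
stress_config <- function(threshold, monitored_cells = 5:8) {
  if (!is.finite(threshold) || threshold > 0) {
    stop("threshold must be a finite pressure head <= 0", call. = FALSE)
  }
  if (length(monitored_cells) == 0L || any(monitored_cells < 1L)) {
    stop("monitored_cells must be a non-empty set of positive indices",
         call. = FALSE)
  }
  structure(list(threshold = threshold,
                 monitored_cells = as.integer(monitored_cells)),
            class = "stress_config")
}

#' Mean root-zone pressure head per time step
#'
#' Unweighted arithmetic mean over the monitored cells of the
#' pressure-head trace, one value per step.
#'
#' @param h_trace Matrix of pressure heads (steps x monitored cells, cm),
#'   e.g. the `$h_monitor` component of a [simulate_column] result.
#' @param cfg A [stress_config]; its `monitored_cells` index the columns
#'   of `h_trace`.
#' @return Numeric vector of per-step mean heads (cm).
#' @export
mean_root_zone_head <- function(h_trace, cfg) {
  h_trace <- as.matrix(h_trace)
  if (nrow(h_trace) == 0L) stop("empty pressure-head trace", call. = FALSE)
  if (max(cfg$monitored_cells) > ncol(h_trace)) {
    stop("monitored_cells exceed the trace width (", ncol(h_trace), ")",
         call. = FALSE)
  }
  rowMeans(h_trace[, cfg$monitored_cells, drop = FALSE])
}

#' Crop stress ratio
#'
#' Fraction of (hourly) steps in which the mean root-zone pressure head
#' lies strictly below the threshold.  Values exactly at the threshold
#' count as unstressed.
#'
#' @param mean_heads Per-step mean root-zone heads (cm), hourly basis.
#' @param threshold Stress threshold (cm).
#' @return The stress ratio, in `[0, 1]`.
#' @export
crop_stress_ratio <- function(mean_heads, threshold) {
  if (length(mean_heads) == 0L) stop("empty head trace", call. = FALSE)
  if (any(!is.finite(mean_heads))) stop("non-finite heads in trace", call. = FALSE)
  mean(mean_heads < threshold)
}
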
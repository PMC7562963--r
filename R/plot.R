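# The classic drainage / stress-risk / ET trade-off figure.

#' Plot the irrigation trade-off figure
#'
#' Against total irrigation (x-axis): cumulative drainage mean with
#' standard-deviation error bars on the left axis, crop stress ratio
#' mean with error bars on the right axis, and a translucent band
#' spanning cumulative ET mean +/- std (left axis).  This is the visual
#' companion of the summary table: the crossing of the falling risk
#' curve and the rising drainage curve frames the strategy choice.
#'
#' @param summary An `ensemble_summary` or a summary data frame with at
#'   least two strategies.
#' @param path Output file; `.png` or `.pdf` by extension.
#' @param width,height Device size in inches.
#' @return Invisibly, the plotted arrays (x, drainage, risk, ET band),
#'   for programmatic inspection.
#' @export
plot_tradeoff <- function(summary, path, width = 7, height = 5) {
  df <- if (inherits(summary, "ensemble_summary")) summary$summary else summary
  if (!is.data.frame(df) || nrow(df) < 2L) {
    stop("need at least 2 strategies to draw a trade-off; ",
         "use the tabular output for a single strategy", call. = FALSE)
  }
  df <- df[order(df$total_irrigation), ]
  x <- df$total_irrigation
  band_lo <- df$et_mean - df$et_std
  band_hi <- df$et_mean + df$et_std

  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 150),
         pdf = grDevices::pdf(path, width = width, height = height),
         stop("unsupported figure format: .", ext, call. = FALSE))
  on.exit(grDevices::dev.off())

  graphics::par(mar = c(5, 4, 2, 4))  # device-local; closed on exit
  ymax <- max(df$drainage_mean + df$drainage_std, band_hi)
  graphics::plot(x, df$drainage_mean, type = "n", ylim = c(0, ymax * 1.05),
                 xlab = "total irrigation (mm)",
                 ylab = "cumulative drainage / ET (mm)")
  graphics::polygon(c(x, rev(x)), c(band_lo, rev(band_hi)), border = NA,
                    col = grDevices::adjustcolor("steelblue", alpha.f = 0.25))
  bar <- df$drainage_std > 0  # zero-length error bars cannot be drawn
  if (any(bar)) {
    graphics::arrows(x[bar], (df$drainage_mean - df$drainage_std)[bar],
                     x[bar], (df$drainage_mean + df$drainage_std)[bar],
                     angle = 90, code = 3, length = 0.04, col = "firebrick")
  }
  graphics::lines(x, df$drainage_mean, type = "b", pch = 19,
                  col = "firebrick")
  graphics::par(new = TRUE)
  graphics::plot(x, df$risk_mean, type = "n", axes = FALSE, xlab = "",
                 ylab = "", ylim = c(0, max(1, df$risk_mean + df$risk_std)))
  bar <- df$risk_std > 0
  if (any(bar)) {
    graphics::arrows(x[bar], pmax(df$risk_mean - df$risk_std, 0)[bar],
                     x[bar], (df$risk_mean + df$risk_std)[bar],
                     angle = 90, code = 3, length = 0.04, col = "darkgreen")
  }
  graphics::lines(x, df$risk_mean, type = "b", pch = 17, col = "darkgreen")
  graphics::axis(4)
  graphics::mtext("crop stress ratio (-)", side = 4, line = 2.5)
  graphics::legend("top", horiz = TRUE, bty = "n", cex = 0.8,
                   legend = c("drainage", "stress ratio", "ET +/- sd"),
                   col = c("firebrick", "darkgreen", "steelblue"),
                   pch = c(19, 17, 15))

  invisible(list(x = x,
                 drainage_mean = df$drainage_mean,
                 drainage_std = df$drainage_std,
                 risk_mean = df$risk_mean, risk_std = df$risk_std,
                 band_lower = band_lo, band_upper = band_hi))
}
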
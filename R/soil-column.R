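# Vertical soil column geometry and the nodal state it carries.
# z is oriented positive downwards (cm); cell 1 is at the surface.

#' Define a uniform 1D soil column
#'
#' Cell-centred finite-volume grid over a single uniform soil profile.
#' The root uptake zone spans all cells whose centres lie within
#' `root_depth` of the surface.
#'
#' @param soil A [soil_params] object (uniform over the profile).
#' @param depth Total column depth (cm).
#' @param n_cells Number of vertical cells (`>= 3`).
#' @param root_depth Depth of the root uptake zone (cm, default 30).
#' @param bottom Bottom boundary: `"free"` for free drainage (unit total
#'   head gradient, outflow `= K` at the bottom cell) or `"sealed"` for a
#'   zero-flux base.
#'
#' @return An object of class `soil_column`.
#' @export
soil_column <- function(soil, depth = 100, n_cells = 100, root_depth = 30,
                        bottom = c("free", "sealed")) {
  bottom <- match.arg(bottom)
  if (!inherits(soil, "soil_params")) stop("soil must be a soil_params object",
                                           call. = FALSE)
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  if (n_cells < 3) stop("n_cells must be >= 3", call. = FALSE)
  if (root_depth <= 0 || root_depth > depth) {
    stop("require 0 < root_depth <= depth", call. = FALSE)
  }
  dz <- depth / n_cells
  z_faces <- seq(0, depth, by = dz)
  z_centers <- z_faces[-1] - dz / 2
  root_cells <- which(z_centers <= root_depth)
  if (length(root_cells) == 0L) {
    stop("no cell centre lies within root_depth; refine the grid",
         call. = FALSE)
  }
  structure(
    list(soil = soil, depth = depth, n_cells = as.integer(n_cells),
         dz = dz, z_centers = z_centers, z_faces = z_faces,
         root_depth = root_depth, root_cells = root_cells, bottom = bottom),
    class = "soil_column")
}

#' @export
print.soil_column <- function(x, ...) {
  cat(sprintf(
    "<soil_column> %.0f cm, %d cells (dz = %.2f cm), roots to %.0f cm, %s bottom\n  soil: %s\n",
    x$depth, x$n_cells, x$dz, x$root_depth, x$bottom, x$soil$name))
  invisible(x)
}

#' Create a column state from a pressure-head or water-content profile
#'
#' The state always carries pressure head and the water content consistent
#' with it through the retention curve.
#'
#' @param col A [soil_column].
#' @param h Pressure head (cm): a scalar (uniform profile) or one value
#'   per cell.  Exactly one of `h` and `theta` must be given.
#' @param theta Water content (ml cm^-3), scalar or per cell; converted
#'   to head through the inverse retention curve.
#' @param t Simulation time (d) attached to the state.
#'
#' @return An object of class `column_state` with fields `h`, `theta`, `t`.
#' @export
column_state <- function(col, h = NULL, theta = NULL, t = 0) {
  if (is.null(h) == is.null(theta)) {
    stop("supply exactly one of h or theta", call. = FALSE)
  }
  if (is.null(h)) {
    theta <- rep_len(theta, col$n_cells)
    h <- pressure_head_from_theta(theta, col$soil)
  }
  h <- rep_len(h, col$n_cells)
  .check_head(h)
  structure(list(h = h, theta = water_content(h, col$soil), t = t),
            class = "column_state")
}

#' Hydrostatic-equilibrium column state
#'
#' No-flow state in which the pressure head increases with depth at
#' exactly the gravitational gradient (`dh/dz = 1` with z positive
#' downwards), anchored at `h_top` in the surface cell.
#'
#' @param col A [soil_column].
#' @param h_top Pressure head in the top cell (cm).
#' @return A [column_state].
#' @export
hydrostatic_state <- function(col, h_top) {
  column_state(col, h = h_top + (col$z_centers - col$z_centers[1]))
}

#' Root water uptake sink term
#'
#' Distributes the potential transpiration demand uniformly over the
#' cells of the root zone, so that the depth integral of the sink equals
#' the demand exactly: `sum(Sr * dz) = Tpot`.
#'
#' @param Tpot Potential transpiration as a flux (cm d^-1), `>= 0`.
#' @param col A [soil_column].
#' @return Per-cell sink strength (ml cm^-3 d^-1), zero below the root
#'   zone.
#' @export
build_sink <- function(Tpot, col) {
  if (!is.finite(Tpot) || Tpot < 0) stop("Tpot must be >= 0", call. = FALSE)
  Sr <- numeric(col$n_cells)
  Sr[col$root_cells] <- Tpot / (length(col$root_cells) * col$dz)
  Sr
}
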
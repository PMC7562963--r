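# Greenhouse evapotranspiration: the De Graaf radiation + heating-pipe
# model and its LAI-based partition into potential transpiration and
# potential soil evaporation.

#' Crop parameters for the greenhouse evapotranspiration model
#'
#' @param a Radiation crop factor (mm cm^2 J^-1), `>= 0`.
#' @param b Heating crop factor (mm per degree C of pipe/air temperature
#'   difference per forcing step), `>= 0`.
#' @param L Current crop length, `0 < L <= Lmax`.
#' @param Lmax Maximum crop length (same unit as `L`).
#' @param LAI Leaf area index (dimensionless), `>= 0`.
#' @param full_grown If `TRUE`, the ET partition short-circuits to
#'   `Tpot = ET`, `Epot = 0` (the full-grown-crop regime in which soil
#'   evaporation is negligible under the closed canopy).
#' @param extinction Canopy light-extinction coefficient used in the
#'   partition (default 0.6; crop-dependent in the wider literature).
#'
#' @return An object of class `et_params`.
#' @export
et_params <- function(a, b, L = 1, Lmax = 1, LAI = 3,
                      full_grown = FALSE, extinction = 0.6) {
  if (a < 0 || b < 0) stop("crop factors a, b must be >= 0", call. = FALSE)
  if (L <= 0 || L > Lmax) stop("require 0 < L <= Lmax", call. = FALSE)
  if (LAI < 0) stop("LAI must be >= 0", call. = FALSE)
  structure(list(a = a, b = b, L = L, Lmax = Lmax, LAI = LAI,
                 full_grown = isTRUE(full_grown), extinction = extinction),
            class = "et_params")
}

#' Greenhouse evapotranspiration (De Graaf model)
#'
#' `ET = (a * R + b * |T_tube - T_gh|) * L / Lmax`, in mm per forcing
#' step.  Radiation drives the daytime demand; at night the temperature
#' difference between the heating pipes and the greenhouse air keeps a
#' smaller demand going.
#'
#' @param R Global + supplementary radiation over the step (J cm^-2),
#'   `>= 0`.
#' @param T_tube Heating-pipe temperature (deg C).
#' @param T_gh Greenhouse indoor air temperature (deg C).
#' @param p An [et_params] object.
#' @return Evapotranspiration (mm per step), `>= 0`; vectorised over the
#'   forcing arguments.
#' @export
degraaf_et <- function(R, T_tube, T_gh, p) {
  if (any(!is.finite(R)) || any(!is.finite(T_tube)) || any(!is.finite(T_gh))) {
    stop("forcing values must be finite", call. = FALSE)
  }
  if (any(R < 0)) stop("radiation cannot be negative", call. = FALSE)
  (p$a * R + p$b * abs(T_tube - T_gh)) * p$L / p$Lmax
}

#' Partition evapotranspiration into transpiration and soil evaporation
#'
#' `Tpot = ET * (1 - exp(-k * LAI))`, `Epot = ET - Tpot`, with extinction
#' coefficient `k` (default 0.6).  The identity `Tpot + Epot = ET` holds
#' exactly by construction.  When `full_grown = TRUE` the canopy is
#' treated as closed and the whole demand is assigned to transpiration.
#'
#' @param ET Evapotranspiration (mm per step), `>= 0`; vectorised.
#' @param LAI Leaf area index, `>= 0`.
#' @param extinction Extinction coefficient `k`.
#' @param full_grown Short-circuit to `Tpot = ET`, `Epot = 0`.
#' @return A list with vectors `Tpot` and `Epot` (mm per step).
#' @export
partition_et <- function(ET, LAI, extinction = 0.6, full_grown = FALSE) {
  if (any(!is.finite(ET)) || any(ET < 0)) stop("ET must be >= 0", call. = FALSE)
  if (!is.finite(LAI) || LAI < 0) stop("LAI must be >= 0", call. = FALSE)
  if (isTRUE(full_grown)) {
    return(list(Tpot = ET, Epot = rep(0, length(ET))))
  }
  Tpot <- ET * (1 - exp(-extinction * LAI))
  list(Tpot = Tpot, Epot = ET - Tpot)
}
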
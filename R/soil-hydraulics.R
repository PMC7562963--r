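# Mualem-Van Genuchten soil hydraulic functions.
#
# All pressure heads are in cm (negative in unsaturated soil), water
# contents in ml cm^-3, conductivities in cm d^-1.

# floor on effective saturation before exponentiation; Kr(S) is singular in
# floating point at S = 0 for some (m, lambda) combinations
.EPS_S <- 1e-12

#' Van Genuchten-Mualem soil hydraulic parameter set
#'
#' Bundles the parameters of the Van Genuchten retention curve and the
#' Mualem conductivity model for one soil type.  The curve-shape parameter
#' `m` is always derived as `m = 1 - 1/n`; it cannot be supplied
#' independently, which prevents silently inconsistent catalogues.
#'
#' @param name Soil-type label.
#' @param theta_r Residual volumetric water content (ml cm^-3).
#' @param theta_s Saturated volumetric water content (ml cm^-3).
#' @param alpha Retention shape parameter (cm^-1), `> 0`.
#' @param n Retention shape parameter (dimensionless), `> 1`.
#' @param Ks Saturated hydraulic conductivity (cm d^-1), `> 0`.
#' @param lam Mualem tortuosity/shape parameter lambda.  Defaults to 0.5,
#'   the classical Mualem value, used when a catalogue omits it.
#' @param class Optional texture-class tag, `"sand"` or `"clay"`.
#'
#' @return An object of class `soil_params`.
#' @examples
#' p <- soil_params("loam", theta_r = 0.078, theta_s = 0.43,
#'                  alpha = 0.036, n = 1.56, Ks = 24.96)
#' water_content(c(-1000, -100, 0), p)
#' @export
soil_params <- function(name, theta_r, theta_s, alpha, n, Ks,
                        lam = 0.5, class = NA_character_) {
  for (v in list(theta_r, theta_s, alpha, n, Ks, lam)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("soil parameters must be finite scalars", call. = FALSE)
    }
  }
  if (theta_r < 0 || theta_r >= theta_s || theta_s > 1) {
    stop("require 0 <= theta_r < theta_s <= 1 (got theta_r = ", theta_r,
         ", theta_s = ", theta_s, ")", call. = FALSE)
  }
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (n <= 1) stop("n must be > 1", call. = FALSE)
  if (Ks <= 0) stop("Ks must be > 0", call. = FALSE)
  if (!is.na(class) && !class %in% c("sand", "clay")) {
    stop("class must be \"sand\" or \"clay\" (or NA)", call. = FALSE)
  }
  structure(
    list(name = as.character(name), theta_r = theta_r, theta_s = theta_s,
         alpha = alpha, n = n, m = 1 - 1 / n, Ks = Ks, lam = lam,
         class = class),
    class = "soil_params")
}

#' @export
print.soil_params <- function(x, ...) {
  cat(sprintf(
    "<soil_params> %s%s\n  theta_r = %.3f  theta_s = %.3f  alpha = %.4f 1/cm\n  n = %.3f (m = %.4f)  Ks = %.2f cm/d  lambda = %.2f\n",
    x$name, if (is.na(x$class)) "" else paste0(" [", x$class, "]"),
    x$theta_r, x$theta_s, x$alpha, x$n, x$m, x$Ks, x$lam))
  invisible(x)
}

.check_head <- function(h) {
  if (!is.numeric(h) || length(h) == 0L || any(!is.finite(h))) {
    stop("pressure head must be finite and numeric", call. = FALSE)
  }
}

#' Effective saturation from pressure head
#'
#' Van Genuchten retention curve
#' `S(h) = (1 + |alpha h|^n)^(-m)` for `h <= 0` and `S = 1` for `h > 0`,
#' with `m = 1 - 1/n`.
#'
#' @param h Pressure head (cm), any finite vector.
#' @param p A [soil_params] object.
#' @return Effective saturation in `(0, 1]`, same length as `h`.
#' @export
effective_saturation <- function(h, p) {
  .check_head(h)
  S <- rep(1, length(h))
  neg <- h < 0
  S[neg] <- (1 + abs(p$alpha * h[neg])^p$n)^(-p$m)
  pmin(pmax(S, .EPS_S), 1)
}

#' Volumetric water content from pressure head
#'
#' `theta(h) = theta_r + S(h) * (theta_s - theta_r)`.
#'
#' @inheritParams effective_saturation
#' @return Water content (ml cm^-3) in `[theta_r, theta_s]`.
#' @export
water_content <- function(h, p) {
  p$theta_r + effective_saturation(h, p) * (p$theta_s - p$theta_r)
}

#' Pressure head from water content (inverse retention curve)
#'
#' Analytic inverse of the retention curve, used to initialise column
#' states from a water-content profile.  Saturation (`theta = theta_s`)
#' maps to `h = 0`.
#'
#' @param theta Water content (ml cm^-3), in `(theta_r, theta_s]`.
#' @param p A [soil_params] object.
#' @return Pressure head (cm), `<= 0`.
#' @export
pressure_head_from_theta <- function(theta, p) {
  if (any(!is.finite(theta)) || any(theta <= p$theta_r) ||
      any(theta > p$theta_s + 1e-12)) {
    stop("theta must lie in (theta_r, theta_s]", call. = FALSE)
  }
  S <- pmin((theta - p$theta_r) / (p$theta_s - p$theta_r), 1)
  h <- numeric(length(S))
  unsat <- S < 1
  h[unsat] <- -(S[unsat]^(-1 / p$m) - 1)^(1 / p$n) / p$alpha
  h
}

#' Relative hydraulic conductivity (Mualem model)
#'
#' `Kr(S) = S^lambda * (1 - (1 - S^(1/m))^m)^2`, so that `Kr(1) = 1` and
#' `Kr(0) = 0`.  `S` is clamped to `[1e-12, 1]` before exponentiation.
#'
#' @param S Effective saturation, in `[0, 1]`.
#' @param p A [soil_params] object.
#' @return Relative conductivity in `[0, 1]`.
#' @export
relative_conductivity <- function(S, p) {
  if (any(!is.finite(S)) || any(S < 0) || any(S > 1 + 1e-12)) {
    stop("S must lie in [0, 1]", call. = FALSE)
  }
  S <- pmin(pmax(S, .EPS_S), 1)
  Kr <- S^p$lam * (1 - pmax(1 - S^(1 / p$m), 0)^p$m)^2
  # map the clamped floor back to an exact zero
  Kr[S <= .EPS_S] <- 0
  Kr
}

#' Hydraulic conductivity from pressure head
#'
#' Composes the retention curve with the Mualem model:
#' `K(h) = Ks * Kr(S(h))`.
#'
#' @inheritParams effective_saturation
#' @return Conductivity (cm d^-1).
#' @export
conductivity <- function(h, p) {
  p$Ks * relative_conductivity(effective_saturation(h, p), p)
}

#' Differential moisture capacity
#'
#' Analytic derivative `C(h) = d theta / d h` of the retention curve,
#' required by the implicit Richards scheme.  `C = 0` for `h >= 0`
#' (the saturated branch is constant) and `C > 0` for `h < 0`.
#'
#' @inheritParams effective_saturation
#' @return Capacity (ml cm^-3 cm^-1), `>= 0`.
#' @export
moisture_capacity <- function(h, p) {
  .check_head(h)
  C <- numeric(length(h))
  neg <- h < 0
  if (any(neg)) {
    u <- abs(p$alpha * h[neg])^p$n
    C[neg] <- (p$theta_s - p$theta_r) * p$m * p$n * p$alpha *
      abs(p$alpha * h[neg])^(p$n - 1) * (1 + u)^(-p$m - 1)
  }
  C
}

# ---- soil catalogue IO -----------------------------------------------------

.CATALOGUE_COLS <- c("name", "class", "theta_r", "theta_s", "alpha", "n",
                     "Ks", "lam")

#' Read a soil-type catalogue
#'
#' A catalogue is a tab-delimited table with columns
#' `name, class, theta_r, theta_s, alpha, n, Ks, lam` and one row per soil
#' type.  A missing `lam` column (or NA cells in it) falls back to the
#' Mualem default 0.5.
#'
#' @param path Path to the catalogue file.
#' @return A list of [soil_params] objects (class `soil_catalogue`).
#' @export
read_soil_catalogue <- function(path) {
  if (!file.exists(path)) stop("catalogue file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- setdiff(.CATALOGUE_COLS, c("lam", names(df)))
  if (length(need)) {
    stop("catalogue is missing columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$lam)) df$lam <- 0.5
  df$lam[is.na(df$lam)] <- 0.5
  cat <- lapply(seq_len(nrow(df)), function(i) {
    soil_params(df$name[i], df$theta_r[i], df$theta_s[i], df$alpha[i],
                df$n[i], df$Ks[i], df$lam[i], df$class[i])
  })
  names(cat) <- df$name
  structure(cat, class = "soil_catalogue")
}

#' Write a soil-type catalogue
#'
#' @param catalogue A list of [soil_params] objects.
#' @param path Output path (tab-delimited text).
#' @return `path`, invisibly.
#' @export
write_soil_catalogue <- function(catalogue, path) {
  if (length(catalogue) == 0L) stop("empty catalogue", call. = FALSE)
  df <- do.call(rbind, lapply(catalogue, function(p) {
    data.frame(name = p$name, class = p$class, theta_r = p$theta_r,
               theta_s = p$theta_s, alpha = p$alpha, n = p$n, Ks = p$Ks,
               lam = p$lam, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset a catalogue by texture class
#'
#' @param catalogue A `soil_catalogue` list.
#' @param class `"sand"` or `"clay"`.
#' @return The entries tagged with `class`, as a `soil_catalogue`.
#' @export
catalogue_class <- function(catalogue, class) {
  if (!class %in% c("sand", "clay")) {
    stop("class must be \"sand\" or \"clay\"", call. = FALSE)
  }
  out <- Filter(function(p) identical(p$class, class), catalogue)
  if (length(out) == 0L) {
    stop("catalogue has no entries of class \"", class, "\"", call. = FALSE)
  }
  structure(out, class = "soil_catalogue")
}
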
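# Implicit solver for the 1D vertical Richards equation
#
#   d(theta)/dt = d/dz ( K dh/dz ) - dK/dz - Sr        [ml cm^-3 d^-1]
#
# with z positive downwards.  Writing the Darcy flux positive downwards,
# q = K (1 - dh/dz), the equation is the finite-volume balance
# d(theta)/dt = (q_in - q_out)/dz - Sr per cell.  Time stepping is
# backward Euler with mass-conservative modified-Picard iteration on the
# mixed theta-h form (the conservative formulation of Celia-type schemes);
# inter-cell conductivities are arithmetic means of the neighbours.

#' Numerical configuration for the Richards solver
#'
#' @param dt_init Initial internal time step (d).  `NULL` means "one
#'   forcing step"; the solver halves it on convergence failure and grows
#'   it back on easy steps.
#' @param dt_min Smallest admissible internal step (d); exhausting the
#'   halving cascade below this is a hard error.
#' @param tol_h Picard convergence tolerance on `max |delta h|` (cm).
#' @param max_iter Maximum Picard iterations per attempted step.
#' @param tol_mb Per-step mass-balance error tolerance (cm of water);
#'   exceeding it is a hard error, since it signals a broken scheme, not
#'   a hard problem.
#' @param monitor_cells Indices of the cells whose pressure heads are
#'   recorded each forcing step (default `1:8`, the "first soil layer").
#' @param h_dry Pressure head (cm) of air-dry soil used to cap the
#'   evaporative surface flux when the top cell cannot sustain the demand.
#'
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dt_init = NULL, dt_min = 1e-6, tol_h = 1e-4,
                          max_iter = 50L, tol_mb = 1e-3,
                          monitor_cells = 1:8, h_dry = -1e5) {
  if (dt_min <= 0 || tol_h <= 0 || tol_mb <= 0) {
    stop("dt_min, tol_h and tol_mb must be positive", call. = FALSE)
  }
  structure(list(dt_init = dt_init, dt_min = dt_min, tol_h = tol_h,
                 max_iter = as.integer(max_iter), tol_mb = tol_mb,
                 monitor_cells = as.integer(monitor_cells), h_dry = h_dry),
            class = "solver_config")
}

# Thomas algorithm for a tridiagonal system; a[1] and c[n] are ignored.
.thomas_solve <- function(a, b, cc, d) {
  n <- length(b)
  cp <- numeric(n)
  dp <- numeric(n)
  cp[1] <- cc[1] / b[1]
  dp[1] <- d[1] / b[1]
  for (i in 2:n) {
    den <- b[i] - a[i] * cp[i - 1]
    if (i < n) cp[i] <- cc[i] / den
    dp[i] <- (d[i] - a[i] * dp[i - 1]) / den
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# Boundary fluxes for a given head profile (cm d^-1, positive downwards).
# The applied surface flux q_app (irrigation minus potential evaporation)
# is capped at the infiltration capacity implied by a saturated surface
# (h_surface = 0) and, on the evaporation side, at the exfiltration
# capacity implied by an air-dry surface (h_surface = h_dry).
.boundary_fluxes <- function(h, K, col, p, q_app, cfg) {
  half <- col$dz / 2
  K_surf <- (p$Ks + K[1]) / 2
  q_cap_in <- K_surf * (1 - h[1] / half)
  q_top <- q_app
  dq_dh1 <- 0  # top-flux sensitivity to h[1] while a capacity cap binds
  if (q_app > q_cap_in) {
    q_top <- q_cap_in
    dq_dh1 <- -K_surf / half
  } else if (q_app < 0) {
    K_dry_face <- (conductivity(cfg$h_dry, p) + K[1]) / 2
    q_cap_out <- min(K_dry_face * (1 - (h[1] - cfg$h_dry) / half), 0)
    if (q_app < q_cap_out) {
      q_top <- q_cap_out
      dq_dh1 <- -K_dry_face / half
    }
  }
  if (col$bottom == "free") {
    n <- col$n_cells
    q_bot <- K[n]
    # chord slope of K at the bottom cell (q_bot = K(h_n) under the unit
    # gradient), used to take the drainage flux implicitly
    dqb_dhn <- if (h[n] < 0) {
      (conductivity(h[n] + 1e-3, p) - K[n]) / 1e-3
    } else 0
  } else {
    q_bot <- 0
    dqb_dhn <- 0
  }
  list(q_top = q_top, q_bot = q_bot, dq_dh1 = dq_dh1, dqb_dhn = dqb_dhn)
}

# One backward-Euler step of length dt by modified-Picard iteration.
# Returns the converged head profile or ok = FALSE for the dt cascade.
.picard_step <- function(h_old, theta_old, col, q_app, Sr, dt, cfg) {
  p <- col$soil
  n <- col$n_cells
  dz <- col$dz
  h <- h_old
  dh_prev <- NULL
  omega <- 1
  for (it in seq_len(cfg$max_iter)) {
    K <- conductivity(h, p)
    Kf <- (K[-n] + K[-1]) / 2
    bc <- .boundary_fluxes(h, K, col, p, q_app, cfg)
    q_int <- Kf * (1 - diff(h) / dz)
    q_in <- c(bc$q_top, q_int)
    q_out <- c(q_int, bc$q_bot)
    theta <- water_content(h, p)
    res <- (theta - theta_old) / dt - (q_in - q_out) / dz + Sr
    # accept on the mass residual as well: near-saturated cells sit on
    # the flat part of theta(h), where the head may chatter at the h = 0
    # kink while the water balance is already closed
    if (sum(abs(res)) * dt * dz < 0.01 * cfg$tol_mb) {
      return(list(ok = TRUE, h = h, iters = it))
    }
    Cc <- moisture_capacity(h, p)
    lower <- c(0, -Kf) / dz^2
    upper <- c(-Kf, 0) / dz^2
    # the specific-storage floor keeps the system nonsingular where
    # C = 0 (saturated cells make the flux-BC problem Neumann-singular);
    # it alters the iteration path only, never the converged solution
    # (dh = 0 still requires res = 0)
    diag_ <- (Cc + 1e-5) / dt + (c(0, Kf) + c(Kf, 0)) / dz^2
    # binding surface caps and free drainage couple the boundary fluxes
    # to the boundary heads; taking them implicitly stabilises the
    # iteration (a binding infiltration cap is a Dirichlet-like ghost)
    diag_[1] <- diag_[1] - bc$dq_dh1 / dz
    diag_[n] <- diag_[n] + bc$dqb_dhn / dz
    dh <- .thomas_solve(lower, diag_, upper, -res)
    # damp overshoot across the sharp saturated/unsaturated transition
    dh <- pmin(pmax(dh, -50), 50)
    # adaptive under-relaxation: a non-shrinking update signals a Picard
    # limit cycle (typical at sharp wetting fronts)
    if (!is.null(dh_prev) && max(abs(dh)) > 0.9 * dh_prev) {
      omega <- max(omega / 2, 0.05)
    } else {
      omega <- min(omega * 1.5, 1)
    }
    dh <- omega * dh
    dh_prev <- max(abs(dh))
    h <- h + dh
    if (any(!is.finite(h))) {
      return(list(ok = FALSE, residual = Inf, iters = it))
    }
    if (max(abs(dh)) < cfg$tol_h) {
      return(list(ok = TRUE, h = h, iters = it))
    }
  }
  list(ok = FALSE, residual = max(abs(dh)), iters = cfg$max_iter)
}

#' Advance the column by one forcing step
#'
#' Integrates the Richards equation over `dt` under constant forcing,
#' sub-stepping internally with a halving cascade when the Picard
#' iteration stalls.  The surface boundary is flux-type:
#' `q_top = q_irr - Epot`, capped at the infiltration capacity (excess
#' irrigation is reported as runoff) and at the exfiltration capacity on
#' the drying side.  Root uptake per cell is capped so the water content
#' cannot fall below `theta_r`; any shortfall is reported as unmet
#' transpiration demand.
#'
#' @param state A [column_state].
#' @param col A [soil_column].
#' @param q_irr Irrigation flux over the step (cm d^-1, `>= 0`).
#' @param Epot Potential soil-evaporation flux (cm d^-1, `>= 0`).
#' @param Tpot Potential transpiration flux (cm d^-1, `>= 0`).
#' @param dt Step length (d, `> 0`).
#' @param cfg A [solver_config].
#'
#' @return A list with the advanced `state` and `fluxes`, the step ledger:
#'   time-averaged `q_top`, `q_bottom`, `uptake`, `runoff`, `unmet_uptake`
#'   (cm d^-1) and the accumulated `mass_balance_error` (cm).
#' @export
richards_step <- function(state, col, q_irr, Epot, Tpot, dt, cfg = solver_config()) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (q_irr < 0 || Epot < 0 || Tpot < 0) {
    stop("q_irr, Epot and Tpot must be >= 0", call. = FALSE)
  }
  p <- col$soil
  dz <- col$dz
  q_app <- q_irr - Epot
  Sr_base <- build_sink(Tpot, col)

  h <- state$h
  theta <- state$theta
  t_done <- 0
  dt_try <- min(if (is.null(cfg$dt_init)) dt else cfg$dt_init, dt)
  acc <- c(infil = 0, drain = 0, uptake = 0, runoff = 0, unmet = 0, mb = 0)

  while (dt - t_done > 1e-12) {
    dt_try <- min(dt_try, dt - t_done)
    # cap uptake at the water available above residual in each root cell;
    # the 1e-3 cushion keeps the dry-end pressure head bounded
    avail <- pmax((theta - p$theta_r - 1e-3) / dt_try, 0)
    Sr <- pmin(Sr_base, avail)
    res <- .picard_step(h, theta, col, q_app, Sr, dt_try, cfg)
    if (!res$ok) {
      if (dt_try / 2 < cfg$dt_min) {
        stop(sprintf(
          "Richards step failed to converge at t = %.6f d (dt = %.2e d, last residual %.3e cm)",
          state$t + t_done, dt_try, res$residual), call. = FALSE)
      }
      dt_try <- dt_try / 2
      next
    }
    h_new <- res$h
    theta_new <- water_content(h_new, p)
    # ledger fluxes recomputed from the converged profile
    K <- conductivity(h_new, p)
    bc <- .boundary_fluxes(h_new, K, col, p, q_app, cfg)
    uptake_rate <- sum(Sr) * dz
    dstor <- sum(theta_new - theta) * dz
    mb <- abs(dstor - (bc$q_top - bc$q_bot - uptake_rate) * dt_try)
    if (mb > cfg$tol_mb) {
      stop(sprintf(
        "mass-balance error %.3e cm exceeds tol_mb at t = %.6f d",
        mb, state$t + t_done), call. = FALSE)
    }
    acc <- acc + c(bc$q_top, bc$q_bot, uptake_rate,
                   max(q_app - bc$q_top, 0), Tpot - uptake_rate, 0) * dt_try
    acc["mb"] <- acc["mb"] + mb
    h <- h_new
    theta <- theta_new
    t_done <- t_done + dt_try
    # grow the step back after easy sub-steps
    if (res$iters <= 5L) dt_try <- dt_try * 2
  }

  new_state <- structure(list(h = h, theta = theta, t = state$t + dt),
                         class = "column_state")
  fluxes <- list(q_top = unname(acc["infil"]) / dt,
                 q_bottom = unname(acc["drain"]) / dt,
                 uptake = unname(acc["uptake"]) / dt,
                 runoff = unname(acc["runoff"]) / dt,
                 unmet_uptake = unname(acc["unmet"]) / dt,
                 mass_balance_error = unname(acc["mb"]))
  list(state = new_state, fluxes = fluxes)
}

#' Simulate a soil column over a forcing series
#'
#' Runs the column through every step of a forcing series: computes the
#' greenhouse evapotranspiration from radiation and temperatures, splits
#' it into transpiration demand (root sink) and soil evaporation (surface
#' flux), applies the selected irrigation strategy, and advances the
#' Richards solver.  Forcing values in mm per step are converted to
#' cm d^-1 internally.
#'
#' @param col A [soil_column].
#' @param initial A [column_state] at the start of the run.
#' @param forcing A [forcing_series].
#' @param et A [et_params] object.
#' @param cfg A [solver_config].
#' @param strategy Index of the irrigation strategy column to apply.
#' @param ET Optional per-step evapotranspiration override (mm per step),
#'   e.g. a bootstrap-resampled series; by default ET is computed from the
#'   forcing with [degraaf_et].
#'
#' @return An object of class `simulation_result`: a per-step ledger
#'   `$steps` (data frame with time, fluxes in cm d^-1 and the per-step
#'   mass-balance error in cm), the monitored pressure-head trace
#'   `$h_monitor` (steps x monitored cells, cm), cumulative totals
#'   `$cumulative` (cm of water), and the final state.
#' @export
simulate_column <- function(col, initial, forcing, et, cfg = solver_config(),
                            strategy = 1L, ET = NULL) {
  stopifnot(inherits(forcing, "forcing_series"), inherits(et, "et_params"))
  spd <- attr(forcing, "steps_per_day")
  n_strat <- length(attr(forcing, "strategies"))
  if (strategy < 1L || strategy > n_strat) {
    stop("strategy index out of range (forcing has ", n_strat, " strategies)",
         call. = FALSE)
  }
  if (any(cfg$monitor_cells < 1L) || any(cfg$monitor_cells > col$n_cells)) {
    stop("monitor_cells outside the column", call. = FALSE)
  }
  dt <- 1 / spd
  mm_to_cmd <- spd / 10  # mm per step -> cm d^-1

  if (is.null(ET)) {
    ET <- degraaf_et(forcing$R, forcing$T_tube, forcing$T_gh, et)
  } else if (length(ET) != nrow(forcing) || any(!is.finite(ET)) || any(ET < 0)) {
    stop("ET override must be a non-negative series matching the forcing",
         call. = FALSE)
  }
  part <- partition_et(ET, et$LAI, et$extinction, et$full_grown)
  irr <- forcing[[attr(forcing, "strategies")[strategy]]]

  n_steps <- nrow(forcing)
  steps <- data.frame(
    t = numeric(n_steps), q_top = numeric(n_steps),
    drainage = numeric(n_steps), transpiration = numeric(n_steps),
    evaporation = numeric(n_steps), runoff = numeric(n_steps),
    unmet_uptake = numeric(n_steps), mb_error = numeric(n_steps))
  h_mon <- matrix(NA_real_, n_steps, length(cfg$monitor_cells))

  state <- initial
  theta0 <- sum(state$theta) * col$dz
  for (i in seq_len(n_steps)) {
    out <- tryCatch(
      richards_step(state, col,
                    q_irr = irr[i] * mm_to_cmd,
                    Epot = part$Epot[i] * mm_to_cmd,
                    Tpot = part$Tpot[i] * mm_to_cmd,
                    dt = dt, cfg = cfg),
      error = function(e) stop("simulation failed at forcing step ", i, ": ",
                               conditionMessage(e), call. = FALSE))
    state <- out$state
    f <- out$fluxes
    # actual surface evaporation is the shortfall of q_top below irrigation,
    # net of runoff (all rates, cm d^-1)
    evap <- irr[i] * mm_to_cmd - f$runoff - f$q_top
    steps[i, ] <- list(state$t, f$q_top, f$q_bottom, f$uptake, evap,
                       f$runoff, f$unmet_uptake, f$mass_balance_error)
    h_mon[i, ] <- state$h[cfg$monitor_cells]
  }

  cum <- list(
    irrigation = sum(irr) / 10,
    infiltration = sum(steps$q_top) * dt,
    drainage = sum(steps$drainage) * dt,
    transpiration = sum(steps$transpiration) * dt,
    evaporation = sum(steps$evaporation) * dt,
    runoff = sum(steps$runoff) * dt,
    et_demand = sum(ET) / 10,
    storage_change = sum(state$theta) * col$dz - theta0,
    mass_balance_error = sum(steps$mb_error))

  structure(list(steps = steps, h_monitor = h_mon, cumulative = cum,
                 final_state = state, col = col, cfg = cfg,
                 strategy = strategy),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cm <- x$cumulative
  cat(sprintf(
    paste0("<simulation_result> %d steps, strategy %d\n",
           "  cumulative (cm): irrigation %.3f | drainage %.3f | transpiration %.3f\n",
           "  evaporation %.3f | runoff %.3f | storage change %+.3f | MB error %.2e\n"),
    nrow(x$steps), x$strategy, cm$irrigation, cm$drainage, cm$transpiration,
    cm$evaporation, cm$runoff, cm$storage_change, cm$mass_balance_error))
  invisible(x)
}
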
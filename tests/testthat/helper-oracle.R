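# Independent brute-force oracle: forward-Euler explicit integration of
# the water balance on the same finite-volume grid, at a tiny fixed time
# step.  Shares only the constitutive closed forms (tested on their own)
# with the implicit solver; the time integration, boundary handling and
# bookkeeping are written independently here.

explicit_simulate <- function(col, h0, q_irr, Epot, Tpot, step_dt,
                              dt_e = 1e-5) {
  p <- col$soil
  n <- col$n_cells
  dz <- col$dz
  theta <- water_content(h0, p)
  h <- h0
  root <- col$root_cells
  drain <- 0
  infil <- 0
  uptake_tot <- 0
  n_sub <- max(1L, round(step_dt / dt_e))
  dt <- step_dt / n_sub
  for (i in seq_along(q_irr)) {
    q_app <- q_irr[i] - Epot[i]
    sink_base <- numeric(n)
    sink_base[root] <- Tpot[i] / (length(root) * dz)
    for (j in seq_len(n_sub)) {
      K <- p$Ks * relative_conductivity(effective_saturation(h, p), p)
      Kf <- (K[-n] + K[-1]) / 2
      q <- Kf * (1 - (h[-1] - h[-n]) / dz)
      q_cap <- (p$Ks + K[1]) / 2 * (1 - h[1] / (dz / 2))
      q_top <- min(q_app, q_cap)
      q_bot <- if (col$bottom == "free") K[n] else 0
      sink <- pmin(sink_base, pmax((theta - p$theta_r - 1e-3) / dt, 0))
      div <- (c(q_top, q) - c(q, q_bot)) / dz
      theta <- theta + dt * (div - sink)
      theta <- pmin(theta, p$theta_s)
      h <- pressure_head_from_theta(theta, p)
      drain <- drain + q_bot * dt
      infil <- infil + q_top * dt
      uptake_tot <- uptake_tot + sum(sink) * dz * dt
    }
  }
  list(h = h, theta = theta, drainage = drain, infiltration = infil,
       uptake = uptake_tot)
}
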
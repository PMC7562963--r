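test_that("a hydrostatic no-flux profile is a fixed point of the solver", {
  p <- loam()
  col <- soil_column(p, 100, 50, bottom = "sealed")
  st <- hydrostatic_state(col, -150)
  state <- st
  for (i in 1:24) {  # one simulated day, hourly steps
    out <- richards_step(state, col, 0, 0, 0, dt = 1 / 24)
    state <- out$state
  }
  expect_lt(max(abs(state$h - st$h)), 1e-3)
  expect_equal(out$fluxes$q_bottom, 0)
  expect_equal(out$fluxes$uptake, 0)
})

test_that("a saturated column under free drainage sheds water at Ks", {
  p <- loam()
  col <- soil_column(p, 100, 20, bottom = "free")
  st <- column_state(col, h = 0)
  out <- richards_step(st, col, 0, 0, 0, dt = 1e-6,
                       cfg = solver_config(dt_min = 1e-8))
  # unit-gradient outflow q = K(h = 0) = Ks at the initial instant
  expect_equal(out$fluxes$q_bottom, p$Ks, tolerance = 0.01)
})

test_that("every step closes its own mass balance under random forcing", {
  set.seed(77)
  for (i in 1:8) {
    p <- random_soil()
    col <- soil_column(p, 100, 25,
                       bottom = sample(c("free", "sealed"), 1))
    st <- column_state(col, h = stats::runif(1, -300, -10))
    q_irr <- stats::runif(1, 0, 5)
    Tpot <- stats::runif(1, 0, 0.6)
    Epot <- stats::runif(1, 0, 0.2)
    s0 <- sum(st$theta) * col$dz
    out <- richards_step(st, col, q_irr, Epot, Tpot, dt = 1 / 24)
    ds <- sum(out$state$theta) * col$dz - s0
    net <- (out$fluxes$q_top - out$fluxes$q_bottom - out$fluxes$uptake) / 24
    expect_lt(abs(ds - net), 1e-3)
    expect_true(all(out$state$theta >= p$theta_r))
    expect_true(all(out$state$theta <= p$theta_s + 1e-12))
  }
})

test_that("a forced 10-day run conserves water to 0.1% of the input", {
  p <- make_soil_catalogue("sand")[["sandy_loam"]]
  fs <- make_forcing(fixture_spec(n_days = 10))
  col <- soil_column(p, 100, 100)
  st <- column_state(col, h = -30)
  res <- simulate_column(col, st, fs, default_et(), solver_config(),
                         strategy = 5)
  cm <- res$cumulative
  closure <- cm$irrigation -
    (cm$storage_change + cm$drainage + cm$transpiration + cm$evaporation +
       cm$runoff)
  expect_lt(abs(closure), 0.001 * cm$irrigation)
  expect_gt(cm$drainage, 0)
  expect_gt(cm$transpiration, 0)
})

test_that("a zero-forcing sealed run leaves the state and ledgers untouched", {
  p <- loam()
  fs <- make_forcing(fixture_spec(n_days = 1, irrigation_daily = c(0, 0),
                                  radiation_peak = 0, t_tube_boost = 0,
                                  noise_radiation = 0, noise_temperature = 0))
  col <- soil_column(p, 60, 20, bottom = "sealed")
  st <- hydrostatic_state(col, -120)
  res <- simulate_column(col, st, fs, default_et(), strategy = 1)
  expect_equal(res$cumulative$drainage, 0)
  expect_equal(res$cumulative$transpiration, 0)
  expect_equal(res$cumulative$irrigation, 0)
  expect_lt(max(abs(res$final_state$h - st$h)), 1e-3)
})

test_that("cumulative drainage self-converges under grid refinement", {
  p <- make_soil_catalogue("sand")[["sandy_loam"]]
  fs <- make_forcing(fixture_spec(n_days = 2, irrigation_daily = c(20)))
  drn <- vapply(c(5, 10, 20, 40), function(nc) {
    col <- soil_column(p, 40, nc, root_depth = 20)
    st <- column_state(col, h = -100)
    simulate_column(col, st, fs, default_et(),
                    solver_config(monitor_cells = 1:3),
                    strategy = 1)$cumulative$drainage
  }, 0)
  gaps <- abs(diff(drn))
  expect_true(all(diff(gaps) < 0))
})

test_that("more irrigation never drains less", {
  p <- make_soil_catalogue("sand")[["sandy_loam"]]
  fs <- make_forcing(fixture_spec(n_days = 3,
                                  irrigation_daily = c(1, 3, 6, 12)))
  drn <- vapply(1:4, function(s) {
    col <- soil_column(p, 100, 25)
    st <- column_state(col, h = -30)
    simulate_column(col, st, fs, default_et(),
                    strategy = s)$cumulative$drainage
  }, 0)
  expect_true(all(diff(drn) >= 0))
})

test_that("excess irrigation beyond infiltration capacity becomes runoff", {
  p <- loam()
  col <- soil_column(p, 50, 20)
  st <- column_state(col, h = -5)
  out <- richards_step(st, col, q_irr = 500, Epot = 0, Tpot = 0, dt = 0.02)
  expect_gt(out$fluxes$runoff, 0)
  # the infiltrating flux stays near the soil's capacity, well below supply
  expect_lt(out$fluxes$q_top, 2 * p$Ks)
  # the balance still closes with the rejected water excluded
  ds <- sum(out$state$theta - st$theta) * col$dz
  expect_lt(abs(ds - (out$fluxes$q_top - out$fluxes$q_bottom) * 0.02), 1e-3)
})

test_that("solver failures carry the failing step index", {
  p <- loam()
  fs <- small_forcing()
  col <- soil_column(p, 100, 10)
  st <- column_state(col, h = -50)
  cfg <- solver_config(dt_min = 0.5, max_iter = 2L)  # cascade cannot help
  expect_error(simulate_column(col, st, fs, default_et(), cfg, strategy = 2),
               "step")
})
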
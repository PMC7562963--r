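test_that("daily ET bootstrap draws uniformly with replacement from the pool", {
  set.seed(1)
  expect_identical(sample_et_series(3.0), 3.0)

  pool <- c(2, 4)
  first_days <- replicate(1e4, sample_et_series(pool)[1])
  expect_true(all(first_days %in% pool))
  # binomial oracle: mean 3, se = 1/sqrt(n)
  expect_lt(abs(mean(first_days) - 3), 3 / sqrt(1e4))

  same <- replicate(50, sample_et_series(rep(5, 7)))
  expect_equal(stats::var(as.numeric(same)), 0)
  expect_error(sample_et_series(numeric(0)), "empty")
})

test_that("soil draws are uniform over the catalogue and seed-reproducible", {
  cat1 <- make_soil_catalogue("sand")[1]
  expect_identical(sample_soil(cat1), cat1[[1]])

  cat4 <- c(make_soil_catalogue("sand"), make_soil_catalogue("clay")[1])
  set.seed(8)
  draws <- replicate(1e4, sample_soil(cat4)$name)
  freqs <- table(draws) / 1e4
  expect_length(freqs, 4)
  expect_true(all(freqs > 0.22 & freqs < 0.28))  # multinomial 3-sigma band

  set.seed(123); a <- replicate(20, sample_soil(cat4)$name)
  set.seed(123); b <- replicate(20, sample_soil(cat4)$name)
  expect_identical(a, b)
  expect_error(sample_soil(list()), "empty")
})

test_that("resampled ET keeps daily totals and within-day shape", {
  fs <- make_forcing(fixture_spec(n_days = 4))
  et <- default_et()
  ET <- degraaf_et(fs$R, fs$T_tube, fs$T_gh, et)
  day <- (seq_len(nrow(fs)) - 1) %/% 24 + 1
  new_daily <- c(2, 7, 4, 4)
  ET2 <- irrisim:::.rescale_daily_et(ET, day, new_daily)
  expect_equal(as.numeric(tapply(ET2, day, sum)), new_daily)
  # shape preserved: within a day the profile is a scalar multiple
  d2 <- which(day == 2)
  expect_equal(ET2[d2] / sum(ET2[d2]), ET[d2] / sum(ET[d2]))
})

test_that("ensemble runs are reproducible and collapse without uncertainty", {
  fs <- make_forcing(fixture_spec(n_days = 2, irrigation_daily = c(3, 9)))
  cat <- make_soil_catalogue("both")
  et <- default_et()
  stress <- stress_config(-80)
  colspec <- list(depth = 60, n_cells = 15)

  spec_off <- uncertainty_spec(FALSE, FALSE, "sand", n_samples = 3, seed = 5)
  ens <- run_ensemble(fs, cat, et, stress, spec_off, colspec)
  # all samples identical per strategy, std exactly zero
  expect_true(all(ens$summary$risk_std == 0))
  expect_true(all(ens$summary$drainage_std == 0))
  expect_true(all(ens$summary$et_std == 0))
  for (s in unique(ens$samples$strategy)) {
    dr <- ens$samples$drainage[ens$samples$strategy == s]
    expect_true(all(dr == dr[1]))
  }

  spec_on <- uncertainty_spec(TRUE, TRUE, "sand", n_samples = 3, seed = 5)
  e1 <- run_ensemble(fs, cat, et, stress, spec_on, colspec)
  e2 <- run_ensemble(fs, cat, et, stress, spec_on, colspec)
  expect_identical(e1$summary, e2$summary)
  expect_identical(e1$samples, e2$samples)
  # a different seed gives different draws
  e3 <- run_ensemble(fs, cat, et, stress,
                     uncertainty_spec(TRUE, TRUE, "sand", 3, seed = 6),
                     colspec)
  expect_false(identical(e1$samples$et, e3$samples$et))
})

test_that("deterministic mode equals the plain simulation", {
  fs <- make_forcing(fixture_spec(n_days = 2, irrigation_daily = c(3, 9)))
  cat <- make_soil_catalogue("both")
  et <- default_et()
  stress <- stress_config(-80)
  spec_off <- uncertainty_spec(FALSE, FALSE, "sand", n_samples = 1, seed = 1)
  ens <- run_ensemble(fs, cat, et, stress, spec_off,
                      list(depth = 60, n_cells = 15), initial_h = -30)

  soil <- catalogue_class(cat, "sand")[[1]]
  col <- soil_column(soil, 60, 15)
  res <- simulate_column(col, column_state(col, h = -30), fs, et,
                         strategy = 2)
  expect_equal(ens$summary$drainage_mean[2], res$cumulative$drainage * 10,
               tolerance = 1e-12)
})

test_that("ensemble mean of bootstrapped ET obeys the law of large numbers", {
  # sampling layer only, no solver
  set.seed(9)
  pool <- stats::runif(12, 1, 6)   # daily ET totals over 12 days
  n <- 1e4
  totals <- replicate(n, sum(sample_et_series(pool)))
  mu <- length(pool) * mean(pool)
  sigma <- sqrt(length(pool) * mean((pool - mean(pool))^2))
  expect_lt(abs(mean(totals) - mu), 3 * sigma / sqrt(n))
  # ensemble spread shrinks with the pool's spread
  narrow <- replicate(n, sum(sample_et_series(pool / 10 + mean(pool) * 0.9)))
  expect_lt(stats::sd(narrow), stats::sd(totals))
})
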
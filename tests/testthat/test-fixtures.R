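test_that("synthetic forcing has the right shape, units and determinism", {
  spec <- fixture_spec(n_days = 2, steps_per_day = 24)
  fs <- make_forcing(spec)
  expect_equal(nrow(fs), 48)

  hour <- (fs$step - 1) %% 24
  night <- hour < 6 | hour >= 18
  expect_true(all(fs$R[night] == 0))
  expect_true(all(fs$R >= 0))

  # daily strategy sums reproduce the specified totals
  day <- (fs$step - 1) %/% 24 + 1
  for (j in seq_along(spec$irrigation_daily)) {
    sums <- tapply(fs[[sprintf("irrigation_%d", j)]], day, sum)
    expect_equal(as.numeric(sums), rep(spec$irrigation_daily[j], 2),
                 tolerance = 1e-9)
  }

  expect_identical(as.data.frame(make_forcing(spec)), as.data.frame(fs))
  spec2 <- fixture_spec(n_days = 2, seed = 43L)
  expect_false(identical(make_forcing(spec2)$R, fs$R))
  expect_error(fixture_spec(n_days = 0), "n_days")
})

test_that("the generated soil catalogue is physically plausible", {
  sands <- make_soil_catalogue("sand")
  clays <- make_soil_catalogue("clay")
  expect_gte(length(sands), 3)
  expect_gte(length(clays), 3)
  for (p in c(sands, clays)) {
    expect_s3_class(p, "soil_params")
    expect_true(p$theta_r < p$theta_s)
    expect_true(p$n > 1)
  }
  min_sand_Ks <- min(vapply(sands, `[[`, 0, "Ks"))
  max_clay_Ks <- max(vapply(clays, `[[`, 0, "Ks"))
  expect_gt(min_sand_Ks, max_clay_Ks)
})

test_that("default fixtures give agronomically sane daily ET", {
  fs <- make_forcing(fixture_spec(n_days = 5))
  ET <- degraaf_et(fs$R, fs$T_tube, fs$T_gh, default_et())
  day <- (fs$step - 1) %/% 24 + 1
  daily <- as.numeric(tapply(ET, day, sum))
  expect_true(all(daily > 0 & daily < 10))  # mm per day
})

test_that("make_fixtures writes a complete, runnable input set", {
  dir <- tempfile()
  cfgp <- make_fixtures(dir, fixture_spec(n_days = 1))
  expect_true(file.exists(file.path(dir, "forcing.tsv")))
  expect_true(file.exists(file.path(dir, "soils.tsv")))
  cfg <- read_run_config(cfgp)
  expect_s3_class(cfg, "run_config")
  expect_equal(nrow(cfg$forcing), 24)
})
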
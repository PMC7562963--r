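test_that("retention closed forms match hand-computed values", {
  p <- n2_soil(alpha = 0.04)  # n = 2, m = 0.5

  expect_identical(effective_saturation(0, p), 1)
  expect_identical(effective_saturation(5, p), 1)
  # h = -1/alpha with n = 2: S = (1 + 1)^(-1/2)
  expect_equal(effective_saturation(-1 / p$alpha, p), 2^(-0.5),
               tolerance = 1e-9)

  expect_identical(water_content(0, p), p$theta_s)
  # S = 0.5 at h = -sqrt(3)/alpha (invert (1+|ah|^2)^(-1/2) = 1/2)
  expect_equal(water_content(-sqrt(3) / p$alpha, p), 0.25, tolerance = 1e-9)
  # dry limit approaches residual content
  expect_equal(water_content(-1e7, p), p$theta_r, tolerance = 1e-4)
})

test_that("Mualem relative conductivity matches its closed form", {
  p <- n2_soil()  # m = 0.5, lam = 0.5
  expect_identical(relative_conductivity(1, p), 1)
  expect_identical(relative_conductivity(0, p), 0)
  expect_equal(relative_conductivity(0.5, p),
               sqrt(0.5) * (1 - sqrt(1 - 0.25))^2, tolerance = 1e-9)
  expect_equal(conductivity(0, p), p$Ks)
})

test_that("inverse retention curve round-trips the pressure head", {
  p <- loam()
  expect_identical(pressure_head_from_theta(p$theta_s, p), 0)
  th <- water_content(-137.5, p)
  expect_equal(pressure_head_from_theta(th, p), -137.5, tolerance = 1e-8)

  set.seed(11)
  for (i in 1:20) {
    ps <- random_soil()
    h <- -10^stats::runif(1, -2, 5)
    expect_equal(pressure_head_from_theta(water_content(h, ps), ps), h,
                 tolerance = 1e-8)
  }
})

test_that("moisture capacity is the analytic derivative of the retention curve", {
  p <- soil_params("sand", 0.045, 0.43, 0.145, 2.68, 712.8)
  expect_identical(moisture_capacity(10, p), 0)
  expect_identical(moisture_capacity(0, p), 0)
  d <- 1e-4
  for (h in c(-0.5, -5, -50, -500, -5000)) {
    fd <- (water_content(h + d, p) - water_content(h - d, p)) / (2 * d)
    expect_gt(moisture_capacity(h, p), 0)
    expect_equal(moisture_capacity(h, p), fd, tolerance = 1e-6)
  }
})

test_that("retention and conductivity curves are monotone and continuous at saturation", {
  set.seed(4)
  for (i in 1:15) {
    p <- random_soil()
    h <- sort(-10^seq(-3, 5, length.out = 60))
    S <- effective_saturation(h, p)
    expect_true(all(diff(S) >= 0))
    Kr <- relative_conductivity(seq(0, 1, length.out = 50), p)
    expect_true(all(diff(Kr) >= -1e-15))
    expect_lt(abs(effective_saturation(-1e-9, p) - 1), 1e-8)
  }
})

test_that("invalid hydraulic inputs are rejected with clear errors", {
  p <- loam()
  expect_error(effective_saturation(NaN, p), "finite")
  expect_error(effective_saturation(Inf, p), "finite")
  expect_error(relative_conductivity(1.5, p), "\\[0, 1\\]")
  expect_error(relative_conductivity(-0.1, p), "\\[0, 1\\]")
  expect_error(pressure_head_from_theta(p$theta_r, p), "theta")
  expect_error(pressure_head_from_theta(p$theta_s + 0.05, p), "theta")
  expect_error(soil_params("bad", 0.3, 0.2, 0.05, 1.5, 10), "theta_r")
  expect_error(soil_params("bad", 0.05, 0.4, 0.05, 1.0, 10), "n must")
  expect_error(soil_params("bad", 0.05, 0.4, -1, 1.5, 10), "alpha")
})

test_that("m is always tied to n and lambda defaults to the Mualem value", {
  p <- soil_params("x", 0.05, 0.4, 0.02, 1.8, 10)
  expect_equal(p$m, 1 - 1 / 1.8)
  expect_equal(p$lam, 0.5)
})

test_that("soil catalogues round-trip through file IO", {
  cat <- make_soil_catalogue("both")
  path <- tempfile(fileext = ".tsv")
  write_soil_catalogue(cat, path)
  back <- read_soil_catalogue(path)
  expect_equal(names(back), names(cat))
  for (nm in names(cat)) expect_equal(back[[nm]], cat[[nm]])
  expect_error(catalogue_class(cat, "peat"), "sand")
  expect_length(catalogue_class(cat, "sand"), 3)
})
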
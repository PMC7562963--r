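# Shared test fixtures, built in code.

loam <- function() {
  soil_params("loam", theta_r = 0.078, theta_s = 0.43, alpha = 0.036,
              n = 1.56, Ks = 24.96)
}

# n = 2 makes the retention closed forms hand-checkable (m = 0.5)
n2_soil <- function(alpha = 0.04) {
  soil_params("n2", theta_r = 0.05, theta_s = 0.45, alpha = alpha, n = 2,
              Ks = 100)
}

random_soil <- function() {
  soil_params("rand",
              theta_r = stats::runif(1, 0, 0.12),
              theta_s = stats::runif(1, 0.3, 0.5),
              alpha = stats::runif(1, 0.005, 0.15),
              n = stats::runif(1, 1.2, 2.8),
              Ks = stats::runif(1, 1, 500),
              lam = stats::runif(1, 0, 1))
}

small_forcing <- function(n_days = 2, irrigation_daily = c(2, 6)) {
  make_forcing(fixture_spec(n_days = n_days,
                            irrigation_daily = irrigation_daily,
                            seed = 99L))
}

default_et <- function() {
  et_params(a = 0.002, b = 0.008, LAI = 3, full_grown = TRUE)
}
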
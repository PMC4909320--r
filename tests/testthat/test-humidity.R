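test_that("the algebraic steady state honours its limiting regimes", {
  # idle chamber: no input, no leak -> the salt's equilibrium value
  p0 <- humidity_params(rh_eq_salt = 75.5, phi_in = 0, k_leak = 0, k_salt = 1)
  expect_equal(humidity_steady_state(p0), 75.5)

  # a near-perfect sink pins RH just above equilibrium
  pfast <- humidity_params(rh_eq_salt = 33.1, phi_in = 5, k_salt = 1e6, k_leak = 0.05)
  expect_equal(humidity_steady_state(pfast), 33.1, tolerance = 1e-3)
  expect_gte(humidity_steady_state(pfast), 33.1)

  # no sink at all: saturation
  expect_warning(
    rh <- humidity_steady_state(humidity_params(rh_eq_salt = 50, phi_in = 1,
                                                k_salt = 0, k_leak = 0)),
    "saturates"
  )
  expect_equal(rh, 100)
})

test_that("kinetic limitation: RH_ss rises with input and falls with salt conductance", {
  rh_of <- function(phi, ks) {
    humidity_steady_state(humidity_params(rh_eq_salt = 54.4, phi_in = phi,
                                          k_salt = ks, k_leak = 0.05))
  }
  phis <- c(0.5, 1, 2, 4, 8, 16)
  rhs <- vapply(phis, rh_of, numeric(1), ks = 2)
  expect_true(all(diff(rhs) > 0))
  expect_true(all(rhs >= 54.4))

  ks <- c(0.5, 1, 2, 4, 8, 16)
  rhs2 <- vapply(ks, function(k) rh_of(5, k), numeric(1))
  expect_true(all(diff(rhs2) < 0))
  expect_true(all(rhs2 >= 54.4))
})

test_that("the simulated RH converges to the algebraic steady state", {
  for (salt in c("LiCl", "NaCl", "Na2SO4")) {
    p <- humidity_params(salt = salt)
    sim <- simulate_humidity(p, duration = 2, dt = 0.5)
    expect_equal(sim$rh_percent[nrow(sim)], humidity_steady_state(p),
                 tolerance = 0.1 / humidity_steady_state(p))
  }
})

test_that("water is conserved through the vapour balance", {
  # k_leak chosen so the post-depletion level stays within the physical
  # range and no saturation clipping masks the bookkeeping
  p <- humidity_params(salt = "NaCl", salt_capacity = 15, k_leak = 0.1)
  sim <- simulate_humidity(p, duration = 8, dt = 0.25)
  cap_ml_per_rh <- 0.0173 * p$chamber_volume / 100
  chamber_change <- (sim$rh_percent - sim$rh_percent[1]) * cap_ml_per_rh
  residual <- sim$input_ml + sim$leak_in_ml - sim$absorbed_ml - chamber_change
  expect_lt(max(abs(residual[-1])) / max(sim$input_ml), 1e-6)
})

test_that("salt depletion switches the sink off and lets RH rise", {
  p <- humidity_params(salt = "NaCl", salt_capacity = 10)
  sim <- simulate_humidity(p, duration = 8, dt = 0.25)
  td <- depletion_time(sim)
  expect_false(is.na(td))
  after <- sim[sim$time_d >= td, ]
  expect_true(all(diff(after$rh_percent) >= -1e-9))
  expect_gt(after$rh_percent[nrow(after)], humidity_steady_state(p) + 5)
  expect_true(all(diff(sim$absorbed_ml) >= 0))
  expect_equal(max(sim$absorbed_ml), 10)

  # depletion clock: capacity over the mean absorption rate while active,
  # with the rate recomputed from the RH trajectory (integral bookkeeping)
  active <- sim$time_d < td
  rate <- p$k_salt * pmax(sim$rh_percent[active] - p$rh_eq_salt, 0)
  expect_equal(td, 10 / mean(rate), tolerance = 0.05)

  # zero capacity behaves as a salt-free chamber from the start
  p0 <- humidity_params(salt = "NaCl", salt_capacity = 0, k_leak = 0.5)
  sim0 <- simulate_humidity(p0, duration = 4)
  expect_equal(sim0$rh_percent[nrow(sim0)], min(100, 50 + 5 / 0.5), tolerance = 0.1)
  expect_true(all(sim0$absorbed_ml == 0))
})

test_that("coarse output steps are sub-stepped to stability", {
  p <- humidity_params(salt = "NaCl", k_salt = 20) # very stiff sink
  sim <- simulate_humidity(p, duration = 3, dt = 12)
  expect_true(all(is.finite(sim$rh_percent)))
  expect_true(all(sim$rh_percent >= 0 & sim$rh_percent <= 100))
  expect_equal(sim$rh_percent[nrow(sim)], humidity_steady_state(p), tolerance = 0.01)
})

test_that("the noisy RH series generator wraps the simulator", {
  p <- humidity_params(salt = "NaCl")
  clean <- generate_rh_series(p, duration = 1, dt = 1, noise_sd = 0, seed = 5)
  sim <- simulate_humidity(p, duration = 1, dt = 1)
  expect_equal(clean$rh_percent, sim$rh_percent)
  expect_equal(clean$time_h, sim$time_d * 24)

  # idle equilibrium: started at equilibrium with no input and no leak,
  # the noise-free series is flat at the salt's RH
  pidle <- humidity_params(rh_eq_salt = 75.5, phi_in = 0, k_leak = 0, k_salt = 2)
  flat <- generate_rh_series(pidle, duration = 2, noise_sd = 0, rh0 = 75.5)
  expect_true(all(flat$rh_percent == 75.5))

  noisy <- generate_rh_series(p, duration = 2, noise_sd = 1.5, seed = 8)
  expect_identical(noisy, generate_rh_series(p, duration = 2, noise_sd = 1.5, seed = 8))
  expect_gt(sd(noisy$rh_percent - noisy$rh_true), 1.0)
  expect_true(all(noisy$rh_percent >= 0 & noisy$rh_percent <= 100))
})
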
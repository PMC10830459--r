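# the dissolved-N2O balance: five terms, solubility, transfer velocity

test_that("production is linear in both substrate fluxes", {
  expect_equal(production(0, 0, 0.001, 0.005), 0)
  expect_equal(production(0, 86400, 0.001, 0.005), 432)
  expect_equal(production(100, 200, 0.001, 0.005),
               2 * production(50, 100, 0.001, 0.005))
  expect_error(production(1, 1, -0.1, 0.5), "yields")
})

test_that("rain deposition is rain volume times equilibrium concentration", {
  expect_equal(rain_deposition(0, 3e-4), 0)
  expect_equal(rain_deposition(1e5, 3e-4), 30)
  expect_error(rain_deposition(-1, 3e-4), "rain_volume")
})

test_that("reduction: nitrate inhibition and the mass cap", {
  p <- default_params()
  expect_equal(reduction(0, 0, 1e6, 20, params = p), 0)
  r0 <- reduction(1e-3, 0, 1e6, 20, params = p)        # nitrate depleted
  r_inf <- reduction(1e-3, 1e6, 1e6, 20, params = p)   # nitrate flooded
  expect_gt(r0, 0)
  expect_lt(r_inf / r0, 1e-6)                          # outcompeted
  # cap at available mass per step
  expect_lte(reduction(10, 0, 1e9, 20, params = p, mass_n2o = 5), 5)
})

test_that("efflux sign convention and arithmetic", {
  expect_equal(efflux(3e-4, 3e-4, 1, 1e6), 0)
  expect_equal(efflux(6e-4, 3e-4, 1, 1e6), 300)
  expect_lt(efflux(1e-4, 3e-4, 1, 1e6), 0)             # influx = sink
  expect_error(efflux(1, 1, -1, 1), "k_gas")
})

test_that("equilibrium concentration matches an independent solubility oracle", {
  # Weiss & Price-type fit coded separately from the package path
  oracle <- function(t_c, ppb) {
    tk <- t_c + 273.15
    f <- exp(-62.7062 + 97.3066 * (100 / tk) + 24.1406 * log(tk / 100))
    f * ppb * 1e-9 * 28 * 1000
  }
  expect_equal(equilibrium_concentration(20, 330), oracle(20, 330))
  # magnitude sanity: a few 1e-4 g N m^-3 at modern mixing ratios
  expect_gt(equilibrium_concentration(20, 330), 1.5e-4)
  expect_lt(equilibrium_concentration(20, 330), 5e-4)
  expect_equal(equilibrium_concentration(20, 0), 0)
  expect_lt(equilibrium_concentration(25, 330), equilibrium_concentration(5, 330))
  # linear in the mixing ratio
  expect_equal(equilibrium_concentration(10, 660),
               2 * equilibrium_concentration(10, 330))
})

test_that("gas transfer velocity: lentic wind form, lotic hydraulic form", {
  p <- default_params()
  expect_equal(gas_transfer_velocity("lentic", wind = 0, params = p),
               p$k_lentic_a)
  expect_equal(gas_transfer_velocity("lentic", wind = 5, params = p),
               p$k_lentic_a + p$k_lentic_b * 25)
  expect_gt(gas_transfer_velocity("lentic", 8, params = p),
            gas_transfer_velocity("lentic", 2, params = p))
  k1 <- gas_transfer_velocity("lotic", depth = 1, velocity = 1,
                              slope = 1e-3, params = p)
  k2 <- gas_transfer_velocity("lotic", depth = 1, velocity = 1,
                              slope = 4e-3, params = p)
  expect_equal(k1, max(p$k_lotic_coef * sqrt(1e-3), p$k_lotic_min))
  expect_gt(k2, k1)
  expect_error(gas_transfer_velocity("swamp"), "lentic")
})

base_element <- function(volume = 1e6, area = 1e4) {
  list(volume = volume, surface_area = area, bed_area = area,
       kind = "lentic", no3_conc = 0, outflow = 0, storage_start = volume,
       inflow_n2o = 0, rain_volume = 0, depth = volume / area,
       velocity = 0, slope = 0)
}

test_that("step_n2o: null step, pure decay, and Eq.-1 closure", {
  p <- default_params(list(k_lentic_a = 0, k_lentic_b = 0, v_red = 0))
  met <- list(temperature = 20, wind = 0, x_atm_ppb = 0)
  out <- step_n2o(base_element(), 50, list(flux_nit = 0, flux_den = 0), met,
                  params = p)
  expect_equal(out$mass, 50)
  expect_equal(sum(abs(out$breakdown)), 0)

  # only reduction active: exact geometric decay (1 - r)^n
  p <- default_params(list(k_lentic_a = 0, k_lentic_b = 0, v_red = 1e-7))
  el <- base_element()
  r <- p$v_red * 86400 * el$bed_area / el$volume       # inhib = 1 at no3 = 0
  m <- 100
  for (i in 1:30) m <- step_n2o(el, m, list(flux_nit = 0, flux_den = 0),
                                met, params = p)$mass
  expect_equal(m, 100 * (1 - r)^30, tolerance = 1e-12)

  # closure property on randomized inputs
  set.seed(12)
  p <- default_params()
  for (i in 1:30) {
    el <- base_element(volume = runif(1, 1e4, 1e7), area = runif(1, 1e3, 1e5))
    el$no3_conc <- runif(1, 0, 2)
    el$outflow <- runif(1, 0, 2 * el$volume)
    el$inflow_n2o <- runif(1, 0, 100)
    el$rain_volume <- runif(1, 0, 1e4)
    met <- list(temperature = runif(1, 0, 30), wind = runif(1, 0, 10),
                x_atm_ppb = 330)
    m0 <- runif(1, 0, 1e4)
    out <- step_n2o(el, m0, list(flux_nit = runif(1, 0, 1e3),
                                 flux_den = runif(1, 0, 1e3)), met, params = p)
    b <- out$breakdown
    lhs <- out$mass - m0
    rhs <- b[["f_a"]] + b[["y_water"]] + b[["d_dep"]] - b[["r_red"]] -
      b[["e_efflux"]]
    expect_lt(abs(lhs - rhs), 1e-9 * max(1, abs(m0), sum(abs(b))))
    expect_gte(out$mass, 0)
  }
})

test_that("constant production converges to the analytic steady state C*", {
  # linear regime: rates slow relative to dt so the operator-split bias is
  # well under the 0.1% assertion
  a <- 0.05                                   # m/d lentic transfer floor
  p <- default_params(list(k_lentic_a = a, k_lentic_b = 0, v_red = 2e-9))
  el <- base_element(volume = 1e6, area = 1e4)
  met <- list(temperature = 20, wind = 0, x_atm_ppb = 330)
  c_eq <- equilibrium_concentration(20, 330)
  y <- 0.05                                   # g N/d production
  r <- p$v_red * 86400 * el$bed_area / el$volume
  kA_V <- a * el$surface_area / el$volume
  rate <- r + kA_V                            # 1/e-folding, per day
  c_star <- (y / el$volume + kA_V * c_eq) / rate
  m <- 0
  n_steps <- ceiling(20 / rate)
  sub <- list(flux_nit = 0, flux_den = y / p$y_den)   # production = y
  for (i in seq_len(n_steps)) m <- step_n2o(el, m, sub, met, params = p)$mass
  expect_equal(m / el$volume, c_star, tolerance = 1e-3)
})
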
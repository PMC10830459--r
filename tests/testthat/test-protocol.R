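# simulation protocol: equilibrium, spin-up, transients, attribution,
# uncertainty. Heavy whole-fixture properties live in test-acceptance.R;
# here everything runs on small worlds or fabricated results.

quiet_trend <- list(t_noise_c = 0, t_anom_sd = 0, precip_noise = 0)

test_that("equilibrium run reaches the analytic single-body fixed point", {
  tau <- 50
  net <- build_world(single_body_tables(tau = tau))
  fc <- generate_forcings(years = 1850:1851, trend = quiet_trend, seed = 1)
  lo <- terrestrial_loads(fc, net, load_response_params())
  eq <- equilibrium_run(net, fc, lo, max_years = 300)
  expect_true(eq$converged)
  # V* = Q * tau, with Q the cell runoff plus rain on the lake surface
  q_in <- net$params$runoff_coef * fc$precip_m[1, 1] * net$cell_area +
    fc$precip_m[1, 1] * net$surf[net$e_body]
  expect_equal(eq$state$V[net$e_body], q_in * tau, tolerance = 0.01)
})

test_that("already-converged input exits after one year; tol is monotone", {
  w <- tiny_world()
  fc <- generate_forcings(years = 1850:1851, trend = quiet_trend, seed = 2)
  lo <- terrestrial_loads(fc, w$network, w$lrp)
  eq1 <- equilibrium_run(w$network, fc, lo, max_years = 200)
  expect_true(eq1$converged)
  eq2 <- equilibrium_run(w$network, fc, lo, state = eq1$state, max_years = 200)
  expect_equal(eq2$years_run, 1)
  loose <- equilibrium_run(w$network, fc, lo, tol = 1e-3, max_years = 200)
  expect_lte(loose$years_run, eq1$years_run)
  # non-convergence warns and still returns the state
  expect_warning(eq3 <- equilibrium_run(w$network, fc, lo, tol = 1e-12,
                                        max_years = 2), "did not converge")
  expect_s3_class(eq3$state, "aquatic_state")
})

test_that("spin-up is seed-deterministic; a one-year pool is plain repetition", {
  w <- tiny_world()
  lo <- terrestrial_loads(w$forcings, w$network, w$lrp)
  st0 <- aquatic_state(w$network)
  a <- spinup_run(w$network, st0, w$forcings, lo, years = 5, seed = 21)
  b <- spinup_run(w$network, st0, w$forcings, lo, years = 5, seed = 21)
  expect_identical(a$state, b$state)
  c <- spinup_run(w$network, st0, w$forcings, lo, years = 5, seed = 22)
  expect_false(identical(a$state$V, c$state$V))

  fc1 <- generate_forcings(years = 1850, trend = quiet_trend, seed = 3)
  lo1 <- terrestrial_loads(fc1, w$network, w$lrp)
  sp <- spinup_run(w$network, st0, fc1, lo1, years = 4, seed = 1)
  st <- set_dam_year(w$network, st0, 1850, natural_flow = TRUE)
  for (i in 1:4) {
    yf <- inlandn2o:::year_forcing(fc1, lo1, 1, w$network$params)
    st <- run_year(w$network, st, yf)$state
  }
  expect_equal(sp$state$V, st$V)
  expect_equal(sp$state$n2o, st$n2o)
})

test_that("all-factors-fixed transient is flat; managed run needs natural", {
  w <- tiny_world("quiet", years = 1850:1869, trend = quiet_trend, seed = 31)
  lo <- terrestrial_loads(w$forcings, w$network, w$lrp)
  eq <- equilibrium_run(w$network, w$forcings, lo, max_years = 200)
  allfix <- scenario("Sfix", c("climate", "co2", "landuse", "ndep", "ag_n"),
                     dams = "off")
  res <- transient_run(w$network, eq$state, allfix, w$forcings, w$lrp)
  s <- annual_series(res, "inland")
  expect_lt(diff(range(s)) / mean(s), 0.02)

  expect_error(transient_run(w$network, eq$state, scenario("S1"),
                             w$forcings, w$lrp),
               "natural")
})

test_that("dams on/off differ only in and below reservoir cells", {
  w0 <- tiny_world("quiet", years = 1850:1869, trend = quiet_trend, seed = 31)
  # same world, but the reservoirs go live inside the simulated window
  tabs <- w0$tables
  tabs$bodies$built_year[tabs$bodies$kind == "reservoir"] <- 1860
  w <- w0
  w$tables <- tabs
  w$network <- build_network(tabs$cells, tabs$reaches, tabs$bodies,
                             w0$network$params)
  net <- w$network
  lo <- terrestrial_loads(w$forcings, net, w$lrp)
  eq <- equilibrium_run(net, w$forcings, lo, max_years = 200)
  nat <- transient_run(net, eq$state, scenario("Snat", dams = "off"),
                       w$forcings, w$lrp)
  man <- transient_run(net, eq$state, scenario("Sman", dams = "on"),
                       w$forcings, w$lrp, natural = nat)
  # cells downstream of (and including) reservoir cells
  res_cells <- unique(net$cell_of[net$is_res])
  affected <- logical(net$n_cells)
  for (c0 in res_cells) {
    cur <- c0
    while (cur > 0 && !affected[cur]) { affected[cur] <- TRUE; cur <- net$down_idx[cur] }
  }
  untouched <- !affected[net$cell_of]
  expect_equal(man$emissions[, untouched], nat$emissions[, untouched],
               tolerance = 1e-12)
  expect_gt(max(abs(man$emissions - nat$emissions)), 0)
})

fake_result <- function(id, fixed, years, emis_total) {
  structure(list(
    scenario = scenario(id, fixed),
    years = years,
    emissions = matrix(emis_total * 1e9, length(years), 1),
    kind = "lake_small", country = "1", cell_of = 1L,
    ag_additions = matrix(0, 1, length(years)),
    residuals = c(0, 0, 0)), class = "scenario_result")
}

test_that("attribution: zero case, closure, and sign preservation", {
  yrs <- 1850:1869
  base <- seq(1, 2, length.out = 20)
  s1 <- fake_result("S1", character(), yrs, base)
  res <- list(S1 = s1,
              S2 = fake_result("S2", "climate", yrs, base),
              S3 = fake_result("S3", "co2", yrs, base))
  att <- attribute(res, c(1850, 1860))
  expect_equal(att$absolute, c(0, 0))

  # fabricated: climate explains 0.3 of a 0.5 net change, co2 -0.1
  s2 <- fake_result("S2", "climate", yrs, base - seq(0, 0.3 * 2 - 0.3 / 20,
                                                     length.out = 20))
  d1 <- attr(attribute(list(S1 = s1, S2 = s2), c(1850, 1860)), "net_change")
  s3 <- fake_result("S3", "co2", yrs, base + seq(0, 0.2, length.out = 20))
  att <- attribute(list(S1 = s1, S2 = s2, S3 = s3), c(1850, 1860))
  expect_equal(attr(att, "net_change"),
               sum(att$absolute) + attr(att, "interaction"))
  expect_lt(att$absolute[att$factor == "co2"], 0)       # sign preserved
  expect_gt(att$absolute[att$factor == "climate"], 0)
  expect_error(attribute(list(S2 = s2), c(1850, 1860)), "S1")
})

test_that("uncertainty ensemble: zero perturbation collapses, default is ordered", {
  w <- tiny_world("quiet", years = 1850:1869, trend = quiet_trend, seed = 31)
  lo <- terrestrial_loads(w$forcings, w$network, w$lrp)
  eq <- equilibrium_run(w$network, w$forcings, lo, max_years = 200)
  nat <- transient_run(w$network, eq$state, scenario("Sn", dams = "off"),
                       w$forcings, w$lrp)
  z <- uncertainty_ensemble(w$network, eq$state, w$forcings, w$lrp,
                            natural = nat,
                            perturbations = c(no3 = 0, nh4 = 0, don = 0,
                                              pon = 0))
  expect_equal(z$decadal$low, z$decadal$high)

  u <- uncertainty_ensemble(w$network, eq$state, w$forcings, w$lrp,
                            natural = nat, center = z$center)
  expect_true(all(u$decadal$high >= u$decadal$center))
  expect_true(all(u$decadal$center >= u$decadal$low))

  # +22% NO3 alone raises emissions sub-linearly
  up <- transient_run(w$network, eq$state, scenario("S1"), w$forcings, w$lrp,
                      natural = nat, load_scale = list(no3 = 1.22))
  m0 <- mean(annual_series(z$center, "inland"))
  m1 <- mean(annual_series(up, "inland"))
  expect_gt(m1, m0)
  expect_lt(m1 / m0 - 1, 0.22)
})

test_that("decadal stats follow the [X0, X9] convention", {
  yrs <- 1850:1879
  s <- seq_along(yrs)
  d <- decadal_stats(s, yrs)
  expect_equal(d$decade, c(1850, 1860, 1870))
  expect_equal(d$mean[1], mean(1:10))
  expect_equal(d$sd[1], sd(1:10))
  expect_equal(d$n, rep(10L, 3))
})
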
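# Vectorised daily engine. One call to engine_day advances every element
# (subnetwork reach, main reach, lentic body) by one day: donor-cell
# advection through the precompiled transfer matrix, then the operator-split
# biogeochemistry (decomposition -> settling/remineralisation ->
# nitrification -> denitrification -> N2O production/deposition ->
# reduction -> air-water exchange). The step self-audits: water, nitrogen
# and per-element N2O balances are recomputed from the applied deltas every
# day and their worst relative residuals are carried in the accumulator, so
# every run reports its own conservation record.

new_accumulator <- function(E) {
  acc <- new.env(parent = emptyenv())
  acc$efflux <- numeric(E)   # net air-water N2O flux, g N (positive up)
  acc$n2 <- numeric(E)       # N2 loss (denitrification + N2O reduction), g N
  acc$denit <- numeric(E)    # NO3 removed by denitrification, g N
  acc$nit <- numeric(E)      # NH4 nitrified, g N
  acc$burial <- numeric(E)   # permanent PON burial, g N
  acc$outlet_water <- 0      # m^3
  acc$outlet_n <- 0          # g N exported at outlets
  acc$in_water <- 0
  acc$in_n <- 0
  acc$max_resid_water <- 0
  acc$max_resid_n <- 0
  acc$max_resid_eq1 <- 0
  acc$limiter_events <- 0L
  acc$days <- 0L
  acc
}

engine_day <- function(net, st, drv, params, acc) {
  dt <- params$dt_days
  E <- net$n_elements
  active <- st$active                  # 1 except pass-through reservoirs
  surf <- net$surf

  f <- net$out_frac
  if (any(st$pass)) f[st$pass] <- 1

  V <- st$V
  out_w <- V * f
  exp_no3 <- st$no3 * f; exp_nh4 <- st$nh4 * f
  exp_don <- st$don * f; exp_pon <- st$pon * f; exp_n2o <- st$n2o * f
  X <- cbind(out_w, exp_no3, exp_nh4, exp_don, exp_pon, exp_n2o)
  IN <- matrix((net$transfer %*% X)@x, E, 6L)

  co <- net$cell_of
  hs <- net$hs_share
  run_in <- hs * drv$runoff_cells[co] * dt            # m^3 this step
  wet <- net$lent_num * active
  rain_vol <- drv$precip_m * surf * wet * dt          # rain hitting open water
  pr_s <- if (params$precip_on_lentic) rain_vol else numeric(E)

  V_new <- V - out_w + IN[, 1] + run_in + pr_s
  if (params$evap_m_d > 0) {
    ev <- pmin(params$evap_m_d * surf * wet * dt, V_new)
    V_new <- V_new - ev
  } else ev <- 0

  w <- drv$w
  if (is.null(drv$loads)) {
    l_no3 <- l_nh4 <- l_don <- l_pon <- numeric(E)
  } else {
    l_no3 <- hs * drv$loads$no3[co] * w
    l_nh4 <- hs * drv$loads$nh4[co] * w
    l_don <- hs * drv$loads$don[co] * w
    l_pon <- hs * drv$loads$pon[co] * w
  }
  tw <- st$tw + (max(drv$tair, 0) - st$tw) / params$temp_smooth_days
  fT0 <- q10_factor(tw, params)
  c_eq <- equilibrium_concentration(tw, drv$x_atm)

  # terrestrial runoff arrives carrying dissolved N2O at atmospheric
  # equilibrium (soil drainage water; a conservative lower bound) — part
  # of the advective term
  l_n2o <- run_in * c_eq

  no3 <- st$no3 - exp_no3 + IN[, 2] + l_no3
  nh4 <- st$nh4 - exp_nh4 + IN[, 3] + l_nh4
  don <- st$don - exp_don + IN[, 4] + l_don
  pon <- st$pon - exp_pon + IN[, 5] + l_pon
  n2o <- st$n2o - exp_n2o + IN[, 6] + l_n2o
  f_a_s <- IN[, 6] + l_n2o - exp_n2o                  # advective N2O, g N/step

  # --- biogeochemistry on post-advection pools, end-of-step volumes ---
  depth <- pmax(V_new / surf, params$depth_floor_m)
  bed <- surf

  a_dec <- (1 - exp(-params$k_dec * fT0 * dt))        # scalar; masked below
  dec <- don * a_dec * active
  don <- don - dec

  fs <- (1 - exp(-(params$v_settle / depth) * dt)) * active
  set_s <- pon * fs
  pon <- pon - set_s
  sed <- st$sed + set_s * params$sed_reminer_frac
  bur_s <- set_s * (1 - params$sed_reminer_frac)
  buried <- st$buried + bur_s
  rem <- sed * ((1 - exp(-params$k_sed * fT0 * dt)) * active)
  sed <- sed - rem

  nh4 <- nh4 + dec + rem
  nit_s <- nh4 * ((1 - exp(-params$k_nit * fT0 * dt)) * active)
  nh4 <- nh4 - nit_s
  no3 <- no3 + nit_s * (1 - params$y_nit)

  hw <- V_new > 0
  invV <- numeric(E); invV[hw] <- 1 / V_new[hw]
  cno3 <- no3 * invV
  damp <- if (params$k_half_no3 > 0) {
    params$k_half_no3 / (cno3 + params$k_half_no3)
  } else 1
  den_rate <- (params$v_den * 86400 * fT0 * dt) * active * cno3 * bed * damp
  den_s <- pmin(den_rate, no3)
  acc$limiter_events <- acc$limiter_events + sum(den_rate > no3 & no3 > 0)
  no3 <- no3 - den_s
  n2_den <- den_s * (1 - params$y_den)

  y_s <- nit_s * params$y_nit + den_s * params$y_den
  d_s <- rain_vol * c_eq
  n2o <- n2o + y_s + d_s

  cno3b <- no3 * invV
  cn2o <- n2o * invV
  inhib <- params$k_half_no3 / (params$k_half_no3 + cno3b + 1e-300)
  red_rate <- (params$v_red * 86400 * fT0 * dt) * active * cn2o * bed * inhib
  red_s <- pmin(red_rate, n2o)
  acc$limiter_events <- acc$limiter_events + sum(red_rate > n2o & n2o > 0)
  n2o <- n2o - red_s

  # air-water exchange integrated exactly over the step (relaxation toward
  # c_eq): unconditionally stable even where k*A*dt >> V (shallow reaches)
  cn2o <- n2o * invV
  klen <- params$k_lentic_a + params$k_lentic_b * drv$wind^2
  klot <- pmax((params$k_lotic_coef * sqrt(params$celerity_ms)) * net$sqrt_slope /
                 sqrt(depth), params$k_lotic_min)
  kgas <- (klen * net$lent_num + klot * (1 - net$lent_num)) * active * hw
  fac <- 1 - exp(-kgas * surf * dt * invV)
  e_s <- (cn2o - c_eq) * V_new * fac
  n2o <- n2o - e_s

  # --- audits -------------------------------------------------------------
  outlet <- net$outlet_e
  out_water <- sum(out_w[outlet])
  out_n <- sum(exp_no3[outlet] + exp_nh4[outlet] + exp_don[outlet] +
                 exp_pon[outlet] + exp_n2o[outlet])
  in_n <- sum(l_no3 + l_nh4 + l_don + l_pon) + sum(d_s) + sum(l_n2o)

  resid_w <- (sum(V_new) + sum(ev) - sum(V)) -
    (sum(run_in) + sum(pr_s) - out_water)
  scale_w <- max(sum(V), sum(run_in) + sum(pr_s), 1)
  acc$max_resid_water <- max(acc$max_resid_water, abs(resid_w) / scale_w)

  tot0 <- sum(st$no3 + st$nh4 + st$don + st$pon + st$sed + st$n2o)
  tot1 <- sum(no3 + nh4 + don + pon + sed + n2o)
  resid_n <- (tot1 - tot0) -
    (in_n - out_n - sum(n2_den) - sum(red_s) - sum(e_s) - sum(bur_s))
  scale_n <- max(tot0, in_n, 1)
  acc$max_resid_n <- max(acc$max_resid_n, abs(resid_n) / scale_n)

  d_m <- n2o - st$n2o
  resid_eq1 <- d_m - (f_a_s + y_s + d_s - red_s - e_s)
  scale_eq1 <- pmax(abs(st$n2o) + abs(f_a_s) + y_s + d_s + red_s + abs(e_s), 1e-12)
  acc$max_resid_eq1 <- max(acc$max_resid_eq1, max(abs(resid_eq1) / scale_eq1))

  acc$efflux <- acc$efflux + e_s
  acc$n2 <- acc$n2 + n2_den + red_s
  acc$denit <- acc$denit + den_s
  acc$nit <- acc$nit + nit_s
  acc$burial <- acc$burial + bur_s
  acc$outlet_water <- acc$outlet_water + out_water
  acc$outlet_n <- acc$outlet_n + out_n
  acc$in_water <- acc$in_water + sum(run_in) + sum(pr_s)
  acc$in_n <- acc$in_n + in_n
  acc$days <- acc$days + 1L

  st$V <- V_new; st$no3 <- no3; st$nh4 <- nh4; st$don <- don
  st$pon <- pon; st$n2o <- n2o; st$sed <- sed; st$buried <- buried
  st$tw <- tw
  st
}

#' Run one simulated year (365 days) through the network
#'
#' @param network a `routing_network`.
#' @param state an `aquatic_state` (with its dam mask already set for the
#'   year via [set_dam_year()]).
#' @param yf year forcing: list with daily vectors `tair`, `precip_m`
#'   (m d^-1), daily load weights `w` (sum 1), scalar `wind` (m s^-1),
#'   scalar `x_atm` (ppb), and `loads` — list of per-cell annual loads
#'   `no3`, `nh4`, `don`, `pon` in g N yr^-1 (or NULL for no loads).
#' @param params parameter list.
#' @return list with `state` and `annual`: per-element annual sums
#'   (`efflux`, `n2`, `denit`, `nit`, `burial`, g N yr^-1), domain totals
#'   and the worst conservation residuals seen during the year.
#' @export
run_year <- function(network, state, yf, params = network$params) {
  acc <- new_accumulator(network$n_elements)
  area <- network$cell_area
  coef <- params$runoff_coef
  drv <- list(runoff_cells = NULL, loads = yf$loads, tair = 0, precip_m = 0,
              wind = yf$wind, x_atm = yf$x_atm, w = 0)
  for (d in seq_along(yf$tair)) {
    drv$runoff_cells <- coef * yf$precip_m[d] * area
    drv$tair <- yf$tair[d]
    drv$precip_m <- yf$precip_m[d]
    drv$w <- yf$w[d]
    state <- engine_day(network, state, drv, params, acc)
  }
  list(state = state, annual = as.list(acc))
}
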
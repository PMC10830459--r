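#' Q10 temperature scaling with a cold-season cutoff
#'
#' All biological transformation rates scale as `q10^((T - t_ref)/10)` and
#' are zeroed when the water temperature falls to or below the configured
#' cold cutoff (an ice-cover stand-in).
#'
#' @param temperature_c water temperature, deg C (vectorised).
#' @param params parameter list from [default_params()].
#' @return dimensionless rate multiplier, >= 0.
#' @export
q10_factor <- function(temperature_c, params = default_params()) {
  f <- params$q10^((temperature_c - params$t_ref) / 10)
  f[temperature_c <= params$cold_cutoff_c] <- 0
  f
}

#' Construct a per-element nitrogen state
#'
#' Masses are in g N. `sed` is the reactive sediment organic-N pool fed by
#' PON settling; `buried` is the cumulative permanent burial.
#' @param no3,nh4,don,pon,sed,buried initial masses, g N.
#' @return list of class `nitrogen_state`.
#' @export
nitrogen_state <- function(no3 = 0, nh4 = 0, don = 0, pon = 0, sed = 0, buried = 0) {
  stopifnot(no3 >= 0, nh4 >= 0, don >= 0, pon >= 0, sed >= 0)
  structure(list(no3 = no3, nh4 = nh4, don = don, pon = pon,
                 sed = sed, buried = buried), class = "nitrogen_state")
}

#' Advect dissolved and particulate species out of an element
#'
#' Donor-cell (upwind) scheme: the outflow carries each species at the
#' element's own concentration, so the exported mass over one step is
#' `mass * min(outflow * dt / storage, 1)`. The fraction is capped at 1, so
#' a full flush exports everything and mass can never go negative; with
#' zero storage the element must hold zero mass and nothing moves.
#'
#' @param state `nitrogen_state` (water-column pools advect; `sed`/`buried`
#'   stay put).
#' @param storage element water volume at the start of the step, m^3.
#' @param outflow outflow rate, m^3 d^-1.
#' @param dt step, days.
#' @return list with `state` (masses after export) and `exported` (named
#'   numeric, g N, one entry per water-column species).
#' @export
advect_species <- function(state, storage, outflow, dt = 1) {
  stopifnot(outflow >= 0, storage >= 0)
  frac <- if (storage > 0) min(outflow * dt / storage, 1) else 0
  sp <- c("no3", "nh4", "don", "pon")
  exported <- vapply(sp, function(s) state[[s]] * frac, numeric(1))
  for (s in sp) state[[s]] <- state[[s]] - exported[[s]]
  list(state = state, exported = exported)
}

#' Decompose dissolved organic nitrogen to ammonium
#'
#' First-order with Q10 scaling, integrated exactly over the step:
#' the transferred mass is `don * (1 - exp(-k_dec * f_T * dt))`.
#'
#' @inheritParams advect_species
#' @param temperature water temperature, deg C.
#' @param params parameter list.
#' @return list with `state` and `flux_dec` (g N d^-1).
#' @export
decompose_don <- function(state, temperature, dt = 1, params = default_params()) {
  fT <- q10_factor(temperature, params)
  moved <- state$don * (1 - exp(-params$k_dec * fT * dt))
  state$don <- state$don - moved
  state$nh4 <- state$nh4 + moved
  list(state = state, flux_dec = moved / dt)
}

#' Settle particulate organic nitrogen to the sediment
#'
#' The settled fraction over a step is `1 - exp(-(v_settle/depth) * dt)`
#' (a purely physical flux, no temperature scaling). Of the settled mass,
#' `sed_reminer_frac` enters the reactive sediment pool and the remainder
#' is permanently buried.
#'
#' @inheritParams decompose_don
#' @param depth water-column depth, m (> 0).
#' @return list with `state` and `flux_settle` (g N d^-1).
#' @export
settle_pon <- function(state, depth, dt = 1, params = default_params()) {
  stopifnot(depth > 0)
  frac <- 1 - exp(-(params$v_settle / depth) * dt)
  settled <- state$pon * frac
  state$pon <- state$pon - settled
  state$sed <- state$sed + settled * params$sed_reminer_frac
  state$buried <- state$buried + settled * (1 - params$sed_reminer_frac)
  list(state = state, flux_settle = settled / dt)
}

#' Remineralise the reactive sediment pool to ammonium
#'
#' First-order with Q10 scaling at rate `k_sed`.
#' @inheritParams decompose_don
#' @return list with `state` and `flux_rem` (g N d^-1).
#' @export
remineralize_sed <- function(state, temperature, dt = 1, params = default_params()) {
  fT <- q10_factor(temperature, params)
  moved <- state$sed * (1 - exp(-params$k_sed * fT * dt))
  state$sed <- state$sed - moved
  state$nh4 <- state$nh4 + moved
  list(state = state, flux_rem = moved / dt)
}

#' Nitrify ammonium to nitrate
#'
#' First-order with Q10 scaling. The total nitrified mass is reported as
#' `flux_nit` (the substrate flux handed to the N2O production term); a
#' fraction `y_nit` of it becomes N2O rather than nitrate, so nitrate
#' receives `(1 - y_nit)` of the converted mass.
#'
#' @inheritParams decompose_don
#' @return list with `state` and `flux_nit` (g N d^-1, total NH4 oxidised).
#' @export
nitrify <- function(state, temperature, dt = 1, params = default_params()) {
  fT <- q10_factor(temperature, params)
  moved <- state$nh4 * (1 - exp(-params$k_nit * fT * dt))
  state$nh4 <- state$nh4 - moved
  state$no3 <- state$no3 + moved * (1 - params$y_nit)
  list(state = state, flux_nit = moved / dt)
}

#' Benthic denitrification of nitrate
#'
#' Flux = `v_den * f_T * [NO3] * bed_area` (uptake-velocity form, v_den in
#' m s^-1) with Michaelis-Menten damping so the rate saturates:
#' the damping factor is `k_half/([NO3]+k_half)`, i.e. the flux equals
#' `v_den * f_T * bed_area * k_half * [NO3]/([NO3]+k_half)` — linear
#' (velocity x concentration x area) for `[NO3] << k_half` and saturating
#' at `v_den * f_T * bed_area * k_half` when nitrate is abundant. Setting
#' `k_half_no3 = 0` disables the damping (pure linear uptake). The flux is
#' capped at the available nitrate mass over the step. Of the removed
#' nitrate, a fraction `y_den` becomes N2O (handed to the N2O balance via
#' `flux_den`) and the remainder is lost as N2.
#'
#' @inheritParams decompose_don
#' @param volume element water volume, m^3 (> 0 for a nonzero flux).
#' @param bed_area benthic (sediment contact) area, m^2.
#' @return list with `state`, `flux_den` (g N d^-1, total NO3 removed) and
#'   `flux_n2` (g N d^-1 lost as N2).
#' @export
denitrify <- function(state, volume, bed_area, temperature, dt = 1,
                      params = default_params()) {
  stopifnot(bed_area > 0)
  conc <- if (volume > 0) state$no3 / volume else 0
  fT <- q10_factor(temperature, params)
  damp <- if (params$k_half_no3 > 0) {
    params$k_half_no3 / (conc + params$k_half_no3)
  } else 1
  rate <- params$v_den * 86400 * fT * conc * bed_area * damp   # g N d^-1
  removed <- min(rate * dt, state$no3)
  state$no3 <- state$no3 - removed
  list(state = state, flux_den = removed / dt,
       flux_n2 = (removed / dt) * (1 - params$y_den))
}
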
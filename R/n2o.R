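#' In-water N2O production
#'
#' Production from the two microbial substrate fluxes:
#' `y_nit * flux_nit + y_den * flux_den`.
#'
#' @param flux_nit total nitrification flux, g N d^-1.
#' @param flux_den total denitrification flux, g N d^-1.
#' @param y_nit,y_den N2O yields in [0, 1].
#' @return production, g N d^-1.
#' @export
production <- function(flux_nit, flux_den, y_nit, y_den) {
  if (any(c(y_nit, y_den) < 0) || any(c(y_nit, y_den) > 1)) {
    stop("yields must lie in [0, 1]", call. = FALSE)
  }
  y_nit * flux_nit + y_den * flux_den
}

#' Dissolved N2O delivered by rain
#'
#' Rain arrives at the atmospheric equilibrium concentration, so the flux
#' is simply `rain_volume * c_eq`, independent of the in-water
#' concentration.
#'
#' @param rain_volume rain falling on the water surface, m^3 d^-1.
#' @param c_eq atmospheric equilibrium N2O concentration, g N m^-3.
#' @return deposition, g N d^-1.
#' @export
rain_deposition <- function(rain_volume, c_eq) {
  if (any(rain_volume < 0)) stop("rain_volume must be >= 0", call. = FALSE)
  rain_volume * c_eq
}

#' Benthic reduction of dissolved N2O to N2
#'
#' Uptake-velocity form `v_red * f_T * [N2O] * bed_area`, modulated by a
#' nitrate inhibition factor `k_half / (k_half + [NO3])`: denitrifiers
#' prefer nitrate as the electron acceptor, so N2O consumption is strongest
#' when nitrate is depleted — the mechanism that lets a water body act as
#' an atmospheric N2O sink. Capped at the available mass per step when
#' `mass_n2o` is supplied.
#'
#' @param n2o_conc dissolved N2O concentration, g N m^-3 (vectorised).
#' @param no3_conc nitrate concentration, g N m^-3.
#' @param bed_area benthic area, m^2.
#' @param temperature water temperature, deg C.
#' @param dt step, days.
#' @param params parameter list.
#' @param mass_n2o optional available mass, g N, for the cap.
#' @return reduction flux, g N d^-1.
#' @export
reduction <- function(n2o_conc, no3_conc, bed_area, temperature, dt = 1,
                      params = default_params(), mass_n2o = Inf) {
  fT <- q10_factor(temperature, params)
  inhib <- params$k_half_no3 / (params$k_half_no3 + no3_conc)
  rate <- params$v_red * 86400 * fT * n2o_conc * bed_area * inhib
  pmin(rate, mass_n2o / dt)
}

#' Air-water N2O exchange flux
#'
#' `k_gas * surface_area * (concentration - c_eq)`; positive values leave
#' to the atmosphere, negative values are influx (the water body is an
#' atmospheric sink). This is the instantaneous flux; the daily step
#' operators ([step_n2o()], the network engine) integrate it exactly over
#' the step as an exponential relaxation toward `c_eq`, which keeps the
#' scheme stable in shallow, fast-exchanging reaches.
#'
#' @param n2o_conc dissolved N2O concentration, g N m^-3.
#' @param c_eq equilibrium concentration, g N m^-3.
#' @param k_gas gas transfer velocity, m d^-1 (>= 0).
#' @param surface_area air-water interface area, m^2 (> 0).
#' @return efflux, g N d^-1 (sign convention: positive to atmosphere).
#' @export
efflux <- function(n2o_conc, c_eq, k_gas, surface_area) {
  if (any(k_gas < 0)) stop("k_gas must be >= 0", call. = FALSE)
  if (any(surface_area <= 0)) stop("surface_area must be > 0", call. = FALSE)
  k_gas * surface_area * (n2o_conc - c_eq)
}

#' Atmospheric equilibrium N2O concentration
#'
#' Henry-solubility equilibrium using a Weiss & Price (1980)-type
#' freshwater (zero-salinity) fit for the N2O solubility function F
#' (mol L^-1 atm^-1):
#' `ln F = -62.7062 + 97.3066 (100/T) + 24.1406 ln(T/100)` with T in
#' kelvin. The equilibrium concentration is linear in the atmospheric
#' mixing ratio and decreases with temperature.
#'
#' @param temperature_c water temperature, deg C (vectorised).
#' @param x_atm_ppb atmospheric N2O mixing ratio, ppb (> 0; 0 allowed and
#'   gives 0).
#' @return equilibrium concentration, g N m^-3 (two N atoms per molecule:
#'   28 g N mol^-1).
#' @export
#' @examples
#' equilibrium_concentration(20, 330)   # ~2.7e-4 g N m^-3
equilibrium_concentration <- function(temperature_c, x_atm_ppb) {
  if (any(x_atm_ppb < 0)) stop("x_atm_ppb must be >= 0", call. = FALSE)
  tk <- temperature_c + 273.15
  lnF <- -62.7062 + 97.3066 * (100 / tk) + 24.1406 * log(tk / 100)
  solub <- exp(lnF)                       # mol L^-1 atm^-1
  solub * (x_atm_ppb * 1e-9) * 28 * 1000  # g N m^-3
}

#' Gas transfer velocity
#'
#' Lentic elements use a quadratic-in-wind form `k = a + b * wind^2`;
#' lotic elements use a hydraulic form
#' `k = k_lotic_coef * sqrt(velocity * slope) / sqrt(depth)`, floored at
#' `k_lotic_min`. Coefficients live in the configuration.
#'
#' @param element_kind `"lentic"` or `"lotic"`.
#' @param wind wind speed at the surface, m s^-1.
#' @param depth water depth, m.
#' @param velocity flow velocity, m s^-1 (lotic).
#' @param slope channel slope, dimensionless (lotic).
#' @param params parameter list.
#' @return transfer velocity, m d^-1.
#' @export
gas_transfer_velocity <- function(element_kind, wind = 0, depth = 1,
                                  velocity = 0, slope = 0,
                                  params = default_params()) {
  if (any(c(wind, depth, velocity, slope) < 0)) {
    stop("gas_transfer_velocity inputs must be >= 0", call. = FALSE)
  }
  if (element_kind == "lentic") {
    params$k_lentic_a + params$k_lentic_b * wind^2
  } else if (element_kind == "lotic") {
    d <- max(depth, params$depth_floor_m)
    max(params$k_lotic_coef * sqrt(velocity * slope) / sqrt(d), params$k_lotic_min)
  } else {
    stop("element_kind must be 'lentic' or 'lotic'", call. = FALSE)
  }
}

#' One daily update of the dissolved-N2O mass balance for one element
#'
#' Applies the five terms of the per-element balance
#' `dM/dt = F_a + Y_water + D - R - E` in the canonical operator-split
#' order (advection, production + rain deposition, reduction, efflux),
#' each term limited so the mass never goes negative, and returns the
#' audited flux breakdown. The identity
#' `(M_new - M_old)/dt = f_a + y_water + d_dep - r_red - e_efflux` holds to
#' machine precision by construction because every term is computed from
#' the mass change it actually caused.
#'
#' @param element list describing the element: `volume` (m^3, end-of-step),
#'   `surface_area` (m^2), `bed_area` (m^2), `kind` (`"lentic"`/`"lotic"`),
#'   `no3_conc` (g N m^-3), `outflow` (m^3 d^-1), `storage_start` (m^3),
#'   `inflow_n2o` (g N d^-1, advective supply from upstream), `rain_volume`
#'   (m^3 d^-1), `depth` (m), `velocity` (m s^-1), `slope`.
#' @param mass_n2o dissolved N2O mass at the start of the step, g N.
#' @param substrates list with `flux_nit` and `flux_den`, g N d^-1.
#' @param met list with `temperature` (water, deg C), `wind` (m s^-1) and
#'   `x_atm_ppb`.
#' @param dt step, days.
#' @param params parameter list.
#' @return list with `mass` (g N) and `breakdown` (named numeric with
#'   `f_a`, `y_water`, `d_dep`, `r_red`, `e_efflux`, g N d^-1).
#' @export
step_n2o <- function(element, mass_n2o, substrates, met, dt = 1,
                     params = default_params()) {
  need <- setdiff(c("temperature", "wind", "x_atm_ppb"), names(met))
  if (length(need)) stop("met is missing: ", paste(need, collapse = ", "),
                         call. = FALSE)
  m0 <- mass_n2o
  # advection: donor-cell export plus upstream supply
  out_frac <- if (element$storage_start > 0) {
    min(element$outflow * dt / element$storage_start, 1)
  } else 0
  exported <- mass_n2o * out_frac
  mass_n2o <- mass_n2o - exported + element$inflow_n2o * dt
  f_a <- element$inflow_n2o - exported / dt

  c_eq <- equilibrium_concentration(met$temperature, met$x_atm_ppb)
  y <- production(substrates$flux_nit, substrates$flux_den,
                  params$y_nit, params$y_den)
  d <- rain_deposition(element$rain_volume, c_eq)
  mass_n2o <- mass_n2o + (y + d) * dt

  conc <- if (element$volume > 0) mass_n2o / element$volume else 0
  r <- reduction(conc, element$no3_conc, element$bed_area, met$temperature,
                 dt, params, mass_n2o = mass_n2o)
  mass_n2o <- mass_n2o - r * dt

  # exchange integrated exactly over the step (stable relaxation to c_eq)
  conc <- if (element$volume > 0) mass_n2o / element$volume else 0
  k <- gas_transfer_velocity(element$kind, met$wind, element$depth,
                             element$velocity, element$slope, params)
  e <- if (element$volume > 0) {
    (conc - c_eq) * element$volume *
      (1 - exp(-k * element$surface_area * dt / element$volume)) / dt
  } else 0
  mass_n2o <- mass_n2o - e * dt

  list(mass = mass_n2o,
       breakdown = c(f_a = f_a, y_water = y, d_dep = d, r_red = r,
                     e_efflux = e))
}
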
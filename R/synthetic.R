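# Synthetic-world generators: drainage topology, lentic inventories, daily
# climate and annual environmental-driver series for 1850-2019, and a
# reduced-form terrestrial load emulator. The emulator deliberately does not
# attempt global realism; it reproduces the *sign structure* the factorial
# attribution relies on — warming and land conversion and N inputs raise
# terrestrial N loads, elevated CO2 suppresses them — with magnitudes
# documented in the methods vignette.

#' Generate a synthetic gridded drainage network
#'
#' Builds a rectangular grid of cells with a random spanning drainage tree
#' to a single outlet (flow directions follow decreasing distance-to-outlet,
#' so the graph is acyclic by construction), channel geometry scaled from
#' upstream cell counts, and a lentic-body inventory drawn from log-uniform
#' ranges spanning both size classes (both classes are guaranteed present
#' whenever at least two bodies are requested). Cell ids are 0-based
#' row-major; coordinates are cell centres; the grid straddles two country
#' codes (western half 1, eastern half 2).
#'
#' @param n_side cells per side (grid is `n_side` x `n_side`).
#' @param n_lakes,n_reservoirs number of lakes / reservoirs (>= 0).
#' @param seed integer seed; fixed seed, identical tables.
#' @param lat0 latitude of the grid centre, degrees.
#' @param params parameter list (grid resolution).
#' @return list of data.frames `cells`, `reaches`, `bodies` conforming to
#'   the [build_network()] schemas.
#' @export
generate_network <- function(n_side = 20, n_lakes = 8, n_reservoirs = 4,
                             seed = 1, lat0 = 45, params = default_params()) {
  stopifnot(n_side >= 1, n_lakes >= 0, n_reservoirs >= 0)
  set.seed(seed)
  res <- params$resolution_deg
  n <- n_side * n_side
  row <- rep(seq_len(n_side), each = n_side) - 1L
  col <- rep(seq_len(n_side), times = n_side) - 1L
  lat <- lat0 + (row - (n_side - 1) / 2) * res
  lon <- (col - (n_side - 1) / 2) * res
  cell_id <- seq_len(n) - 1L          # 0-based row-major

  # outlet at the grid centre-south; drain along decreasing BFS distance
  outlet <- which(row == 0 & col == n_side %/% 2)
  dist <- abs(row - row[outlet]) + abs(col - col[outlet])
  down <- integer(n)
  for (i in seq_len(n)) {
    if (i == outlet) { down[i] <- -1L; next }
    nb <- c(if (row[i] > 0) i - n_side, if (row[i] < n_side - 1) i + n_side,
            if (col[i] > 0) i - 1L, if (col[i] < n_side - 1) i + 1L)
    nb <- nb[dist[nb] < dist[i]]
    down[i] <- cell_id[if (length(nb) == 1) nb else sample(nb, 1)]
  }
  country <- ifelse(col < n_side / 2, 1L, 2L)
  cells <- data.frame(cell_id = cell_id, lat = lat, lon = lon,
                      downstream_id = down, country_code = country)

  # upstream cell counts for channel geometry
  idx_down <- ifelse(down == -1L, 0L, down + 1L)
  nup <- rep(1L, n)
  for (i in order(-dist)) if (idx_down[i] > 0) nup[idx_down[i]] <- nup[idx_down[i]] + nup[i]
  carea <- cell_area_from_latitude(lat, res)
  side <- sqrt(carea)
  reaches <- rbind(
    data.frame(cell_id = cell_id, corridor = "subnetwork",
               length_m = 3.0 * side, width_m = 5,
               slope = stats::runif(n, 8e-4, 2e-3)),
    data.frame(cell_id = cell_id, corridor = "main",
               length_m = 1.2 * side, width_m = 10 + 4 * sqrt(nup),
               slope = stats::runif(n, 2e-4, 8e-4))
  )

  nb_tot <- n_lakes + n_reservoirs
  if (nb_tot > 0) {
    bcell <- sample(cell_id, nb_tot, replace = nb_tot > n)
    area <- 10^stats::runif(nb_tot, 6, 8.7)          # 1 km^2 .. ~500 km^2
    depth <- 10^stats::runif(nb_tot, 0.3, 1.4)       # 2 .. 25 m
    resid <- 10^stats::runif(nb_tot, 1.5, 3.2)       # ~30 .. 1600 d
    ca_b <- carea[match(bcell, cell_id)]
    up <- 10^stats::runif(nb_tot, -1.5, 1.5) * ca_b  # spans both classes
    if (nb_tot >= 2) {                               # guarantee both classes
      up[1] <- 0.3 * ca_b[1]
      up[2] <- 3.0 * ca_b[2]
    }
    kind <- c(rep("lake", n_lakes), rep("reservoir", n_reservoirs))
    built <- ifelse(kind == "reservoir",
                    sample(1900:2000, nb_tot, replace = TRUE), NA_real_)
    bodies <- data.frame(
      body_id = paste0("B", seq_len(nb_tot)), cell_id = bcell, kind = kind,
      area_m2 = area, volume_m3 = area * depth, depth_m = depth,
      residence_days = resid, upstream_m2 = up, built_year = built)
  } else {
    bodies <- NULL
  }
  list(cells = cells, reaches = reaches, bodies = bodies)
}

#' Generate daily climate and annual driver series for 1850-2019
#'
#' Daily climate is a seasonal sinusoid with weather noise and a warming
#' trend that is flat before 1901 (emulating a stationary pre-20th-century
#' climate block) and ramps linearly to `warming_c` by 2019. Annual
#' drivers: an accelerating CO2 ramp; N deposition rising with
#' industrialisation; manure growing slowly from 1850; synthetic fertilizer
#' zero before its onset year (default 1910) then following a logistic so
#' the manure share of agricultural N declines from 100% toward ~55% by the
#' 1990s; cropland fraction expanding through the period.
#'
#' @param years calendar years (default 1850:2019).
#' @param trend named list overriding trend parameters: `warming_c`,
#'   `t_mean_c`, `t_amp_c`, `t_noise_c`, `precip_mm_d`, `precip_trend`,
#'   `co2_0`, `co2_rise`, `ndep_0`, `ndep_rise`, `fert_max`, `fert_mid`,
#'   `fert_scale`, `fert_onset`, `manure_0`, `manure_rise`, `crop_0`,
#'   `crop_rise`, `wind_ms`.
#' @param seed integer seed for the weather noise.
#' @return a `forcing_series` list: daily matrices (`years` x 365) `tair`,
#'   `tmax`, `tmin`, `sw`, `precip_m`; annual vectors `co2`, `ndep`,
#'   `fert`, `manure`, `cropfrac` (kg N ha^-1 yr^-1 for the N series);
#'   scalar `wind_ms`; the resolved trend parameters and seed.
#' @export
generate_forcings <- function(years = 1850:2019, trend = list(), seed = 1) {
  tp <- list(warming_c = 1.3, t_mean_c = 9, t_amp_c = 12, t_noise_c = 2,
             t_anom_sd = 0.3, precip_noise = 1,
             precip_mm_d = 2.4, precip_trend = 0, co2_0 = 285, co2_rise = 125,
             ndep_0 = 1.5, ndep_rise = 8.5, fert_max = 30, fert_mid = 1975,
             fert_scale = 12, fert_onset = 1910, manure_0 = 8,
             manure_rise = 27, crop_0 = 0.10, crop_rise = 0.30, wind_ms = 3)
  unknown <- setdiff(names(trend), names(tp))
  if (length(unknown)) stop("unknown trend parameter(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  tp[names(trend)] <- trend
  set.seed(seed)
  ny <- length(years)
  doy <- seq_len(365)
  season_t <- -cos(2 * pi * (doy - 15) / 365)        # coldest mid-January
  frac <- pmin(pmax((years - 1901) / (2019 - 1901), 0), 1)
  warm <- tp$warming_c * frac
  tair <- matrix(0, ny, 365)
  precip <- matrix(0, ny, 365)
  for (y in seq_len(ny)) {
    anom <- stats::rnorm(1, 0, tp$t_anom_sd)
    tair[y, ] <- tp$t_mean_c + warm[y] + anom + tp$t_amp_c * season_t +
      stats::rnorm(365, 0, tp$t_noise_c)
    p_mean <- tp$precip_mm_d * (1 + tp$precip_trend * frac[y])
    precip[y, ] <- if (tp$precip_noise > 0) {
      stats::rgamma(365, shape = 0.8 / tp$precip_noise^2,
                    rate = 0.8 / tp$precip_noise^2 / p_mean) / 1000
    } else rep(p_mean / 1000, 365)
  }
  fshare <- pmin(pmax((years - 1850) / (2019 - 1850), 0), 1)
  fert <- tp$fert_max / (1 + exp(-(years - tp$fert_mid) / tp$fert_scale))
  fert[years < tp$fert_onset] <- 0
  structure(list(
    years = years,
    tair = tair, tmax = tair + 4, tmin = tair - 4,
    sw = matrix(rep(250 + 100 * season_t, each = ny), ny, 365),
    precip_m = precip,
    co2 = tp$co2_0 + tp$co2_rise * fshare^2.2,
    ndep = tp$ndep_0 + tp$ndep_rise * fshare^1.5,
    fert = fert,
    manure = tp$manure_0 + tp$manure_rise * fshare,
    cropfrac = pmin(tp$crop_0 + tp$crop_rise * fshare^1.2, 1),
    wind_ms = tp$wind_ms, trend = tp, seed = seed
  ), class = "forcing_series")
}

#' Terrestrial load-response parameters
#'
#' Reduced-form emulator coefficients. `base` are natural per-area export
#' rates (g N m^-2 yr^-1) per species; `s_temp` scales the base export per
#' degC of annual warming; `s_crop` per unit cropland fraction;
#' `leach_frac` is the fraction of N inputs (fertilizer + manure on
#' cropland, deposition everywhere) leached to waters, split across
#' species by `leach_split`; `s_co2` (>= 0, acts with a negative sign) is
#' the fractional suppression of the base export per ppm CO2 above
#' `co2_ref`.
#'
#' @param override named list of replacements.
#' @return list of class `load_response_params`.
#' @export
load_response_params <- function(override = list()) {
  p <- list(
    base = c(no3 = 0.05, nh4 = 0.01, don = 0.04, pon = 0.03),
    s_temp = 0.08, s_crop = 2.0,
    leach_frac = 0.15,
    leach_split = c(no3 = 0.7, nh4 = 0.1, don = 0.1, pon = 0.1),
    s_co2 = 0.004, co2_ref = 285,
    crop_noise_sd = 0.3
  )
  unknown <- setdiff(names(override), names(p))
  if (length(unknown)) stop("unknown load parameter(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  p[names(override)] <- override
  stopifnot(p$leach_frac >= 0, p$leach_frac <= 1, p$s_co2 >= 0,
            abs(sum(p$leach_split) - 1) < 1e-9)
  structure(p, class = "load_response_params")
}

#' Terrestrial nitrogen loads from the forcing series
#'
#' Annual per-cell loads for each species (g N yr^-1):
#' `base * area * (1 + s_temp * dT) * (1 + s_crop * crop_cell)` minus the
#' CO2 suppression term `s_co2 * (CO2 - co2_ref) * base * area` (applied to
#' the natural export only, so the response to agricultural N stays exactly
#' linear), plus `leach_frac * leach_split * N_inputs`, floored at zero.
#' N inputs per cell combine fertilizer and manure applied to the cell's
#' cropland with deposition over the whole cell. Daily disaggregation
#' weights follow daily runoff (i.e. precipitation).
#'
#' @param forcings a `forcing_series`.
#' @param network a `routing_network` (cell areas, per-cell cropland noise
#'   keyed to the forcing seed).
#' @param lrp `load_response_params`.
#' @return list with `loads` — a `[n_cells, n_years, 4]` array (g N yr^-1,
#'   species no3/nh4/don/pon) — `w` — `[n_years, 365]` daily weights
#'   (rows sum to 1) — and `ag_additions` — per-cell annual agricultural N
#'   additions (fertilizer + manure, g N yr^-1), the EF denominator.
#' @export
terrestrial_loads <- function(forcings, network, lrp = load_response_params()) {
  ny <- length(forcings$years)
  n <- network$n_cells
  area <- network$cell_area
  set.seed(forcings$seed + 1000L)   # spatial pattern tied to the forcing seed
  crop_mult <- exp(stats::rnorm(n, 0, lrp$crop_noise_sd))
  tann <- rowMeans(forcings$tair)
  tbase <- tann[1]
  sp <- c("no3", "nh4", "don", "pon")
  loads <- array(0, dim = c(n, ny, 4), dimnames = list(NULL, NULL, sp))
  ag_add <- matrix(0, n, ny)
  for (y in seq_len(ny)) {
    crop_cell <- pmin(forcings$cropfrac[y] * crop_mult, 1)
    # kg N ha^-1 yr^-1 -> g N m^-2 yr^-1 is x 0.1
    ag_gm2 <- (forcings$fert[y] + forcings$manure[y]) * 0.1 * crop_cell
    nin <- (ag_gm2 + forcings$ndep[y] * 0.1) * area        # g N yr^-1
    ag_add[, y] <- ag_gm2 * area
    ft <- 1 + lrp$s_temp * (tann[y] - tbase)
    co2_term <- lrp$s_co2 * (forcings$co2[y] - lrp$co2_ref)
    for (k in seq_along(sp)) {
      b <- lrp$base[[sp[k]]] * area
      loads[, y, k] <- pmax(
        b * ft * (1 + lrp$s_crop * crop_cell) - co2_term * b +
          lrp$leach_frac * lrp$leach_split[[sp[k]]] * nin, 0)
    }
  }
  psum <- rowSums(forcings$precip_m)
  w <- forcings$precip_m / ifelse(psum > 0, psum, 1)
  w[psum == 0, ] <- 1 / 365
  list(loads = loads, w = w, ag_additions = ag_add)
}

#' The packaged reference world
#'
#' A 20 x 20 grid with 8 lakes and 4 reservoirs (both size classes
#' present), full 1850-2019 forcings, and default load-response
#' parameters, regenerated bit-identically from its fixed seeds.
#'
#' @param seed base seed (default 42; the forcing seed is `seed + 1`).
#' @param params parameter list.
#' @param n_side,n_lakes,n_reservoirs world dimensions (recorded in run
#'   manifests so the world is reconstructible).
#' @param years simulation years.
#' @param trend forcing trend overrides (see [generate_forcings()]).
#' @param lrp load-response parameters.
#' @return list with `tables`, `network`, `forcings`, `lrp`, `seed`, `dims`.
#' @export
reference_fixture <- function(seed = 42, params = default_params(),
                              n_side = 20, n_lakes = 8, n_reservoirs = 4,
                              years = 1850:2019, trend = list(),
                              lrp = load_response_params()) {
  tabs <- generate_network(n_side = n_side, n_lakes = n_lakes,
                           n_reservoirs = n_reservoirs,
                           seed = seed, params = params)
  net <- build_network(tabs$cells, tabs$reaches, tabs$bodies, params)
  fc <- generate_forcings(years = years, trend = trend, seed = seed + 1)
  list(tables = tabs, network = net, forcings = fc, lrp = lrp, seed = seed,
       dims = list(n_side = n_side, n_lakes = n_lakes,
                   n_reservoirs = n_reservoirs,
                   year_min = min(years), year_max = max(years)))
}
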
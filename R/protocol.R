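# The four-stage simulation protocol: equilibrium run at first-year
# forcing, a 30-year spin-up over randomised 1850s climate, a natural-flow
# transient (dams deactivated) and a dam-managed transient, plus the five
# factorial experiments that each hold one environmental factor at its
# first-year value, and the load-perturbation uncertainty ensemble.

FACTORS <- c("climate", "co2", "landuse", "ndep", "ag_n")

#' Define a factorial scenario
#'
#' @param scenario_id short label (e.g. "S1").
#' @param fixed_factors subset of `c("climate","co2","landuse","ndep","ag_n")`
#'   held at their first-year values (empty for the all-transient run).
#' @param dams `"on"` (managed flow) or `"off"` (natural flow).
#' @param seed integer recorded in the manifest.
#' @return list of class `scenario`.
#' @export
scenario <- function(scenario_id, fixed_factors = character(),
                     dams = c("on", "off"), seed = 0L) {
  dams <- match.arg(dams)
  bad <- setdiff(fixed_factors, FACTORS)
  if (length(bad)) stop("unknown factor(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(scenario_id = scenario_id, fixed_factors = fixed_factors,
                 dams = dams, seed = as.integer(seed)), class = "scenario")
}

#' The canonical six scenarios
#'
#' S1 is the all-combined run (every driver transient, dams managed);
#' S2-S6 each fix exactly one factor at its first-year value: climate, CO2,
#' land use, N deposition, agricultural N.
#' @return named list of `scenario` objects.
#' @export
default_scenarios <- function() {
  list(S1 = scenario("S1"),
       S2 = scenario("S2", "climate"),
       S3 = scenario("S3", "co2"),
       S4 = scenario("S4", "landuse"),
       S5 = scenario("S5", "ndep"),
       S6 = scenario("S6", "ag_n"))
}

#' Hold selected forcing factors at their first-year values
#'
#' @param forcings a `forcing_series`.
#' @param fixed_factors character vector of factors to freeze.
#' @return modified `forcing_series`.
#' @export
freeze_forcings <- function(forcings, fixed_factors) {
  ny <- length(forcings$years)
  rep1 <- function(x) rep(x[1], ny)
  if ("climate" %in% fixed_factors) {
    for (m in c("tair", "tmax", "tmin", "sw", "precip_m")) {
      forcings[[m]] <- matrix(forcings[[m]][1, ], ny, 365, byrow = TRUE)
    }
  }
  if ("co2" %in% fixed_factors)     forcings$co2 <- rep1(forcings$co2)
  if ("landuse" %in% fixed_factors) forcings$cropfrac <- rep1(forcings$cropfrac)
  if ("ndep" %in% fixed_factors)    forcings$ndep <- rep1(forcings$ndep)
  if ("ag_n" %in% fixed_factors) {
    forcings$fert <- rep1(forcings$fert)
    forcings$manure <- rep1(forcings$manure)
  }
  forcings
}

# assemble the run_year forcing bundle for year index y
year_forcing <- function(forcings, loads_obj, y, params, load_scale = NULL) {
  ld <- list(no3 = loads_obj$loads[, y, "no3"], nh4 = loads_obj$loads[, y, "nh4"],
             don = loads_obj$loads[, y, "don"], pon = loads_obj$loads[, y, "pon"])
  if (!is.null(load_scale)) for (s in names(load_scale)) ld[[s]] <- ld[[s]] * load_scale[[s]]
  list(tair = forcings$tair[y, ], precip_m = forcings$precip_m[y, ],
       w = loads_obj$w[y, ], wind = forcings$wind_ms,
       x_atm = x_atm_for_year(forcings$years[y], params), loads = ld)
}

state_pools <- function(st) {
  c(V = sum(st$V), no3 = sum(st$no3), nh4 = sum(st$nh4), don = sum(st$don),
    pon = sum(st$pon), sed = sum(st$sed), n2o = sum(st$n2o))
}

#' Equilibrium run at first-year forcing
#'
#' Repeats the first simulation year until the maximum relative
#' interannual change over every state pool (water, the four N species,
#' sediment, dissolved N2O) drops below `tol`, or `max_years` is reached
#' (then a warning carries the residual and the state is still returned).
#'
#' @param network a `routing_network`.
#' @param forcings a `forcing_series` (only year 1 is used).
#' @param loads_obj output of [terrestrial_loads()] on the same forcings.
#' @param params parameter list.
#' @param tol convergence tolerance on relative pool change (default 1e-4).
#' @param max_years cap on iterations (default 500).
#' @param state optional starting `aquatic_state`.
#' @param dams_off logical; pre-industrial equilibrium runs with dams
#'   deactivated (no reservoir predates 1850 in the synthetic world).
#' @return list with `state`, `years_run`, `converged`, `resid`.
#' @export
equilibrium_run <- function(network, forcings, loads_obj,
                            params = network$params, tol = 1e-4,
                            max_years = 500, state = NULL, dams_off = TRUE) {
  if (is.null(state)) state <- aquatic_state(network)
  state <- set_dam_year(network, state, forcings$years[1], natural_flow = dams_off)
  yf <- year_forcing(forcings, loads_obj, 1, params)
  prev <- state_pools(state)
  resid <- Inf; years_run <- 0L
  while (years_run < max_years) {
    state <- run_year(network, state, yf, params)$state
    years_run <- years_run + 1L
    cur <- state_pools(state)
    resid <- max(abs(cur - prev) / pmax(abs(prev), 1e-9))
    prev <- cur
    if (resid < tol) break
  }
  converged <- resid < tol
  if (!converged) warning("equilibrium run did not converge: residual ",
                          signif(resid, 3), " after ", years_run, " years")
  list(state = state, years_run = years_run, converged = converged,
       resid = resid)
}

#' 30-year spin-up over randomised 1850s climate
#'
#' Steps the state through `years` simulated years whose forcing years are
#' drawn uniformly with replacement from the first decade of the forcing
#' series under the given seed (recorded in the run manifest).
#'
#' @inheritParams equilibrium_run
#' @param years spin-up length (default 30).
#' @param seed integer seed for the year draw.
#' @return list with `state` and `drawn_years`.
#' @export
spinup_run <- function(network, state, forcings, loads_obj,
                       params = network$params, years = 30, seed = 0L,
                       dams_off = TRUE) {
  pool <- seq_len(min(10, length(forcings$years)))
  set.seed(seed)
  draws <- sample(pool, years, replace = TRUE)
  state <- set_dam_year(network, state, forcings$years[1], natural_flow = dams_off)
  for (y in draws) {
    yf <- year_forcing(forcings, loads_obj, y, params)
    state <- run_year(network, state, yf, params)$state
  }
  list(state = state, drawn_years = forcings$years[draws])
}

#' Transient run 1850-2019 under one scenario
#'
#' Freezes the scenario's fixed factors, recomputes terrestrial loads for
#' the frozen world, and steps every year. Dams activate per construction
#' year in managed (`dams = "on"`) runs; natural-flow runs deactivate all
#' dams. A managed run requires the natural-flow result as its baseline
#' (`natural`), enforcing the protocol ordering.
#'
#' @param network a `routing_network`.
#' @param state post-spin-up `aquatic_state` (the common branch point).
#' @param scen a [scenario()].
#' @param forcings the unfrozen `forcing_series`.
#' @param lrp `load_response_params`.
#' @param params parameter list.
#' @param natural the natural-flow `scenario_result` (required for managed
#'   runs).
#' @param load_scale optional named multipliers on terrestrial loads by
#'   species (the uncertainty ensemble's knob).
#' @return a `scenario_result`: per-element annual net efflux matrix
#'   (g N yr^-1), per-element annual N2/denitrification/burial diagnostics,
#'   element metadata, per-cell agricultural additions, and the worst
#'   conservation residuals across the whole run.
#' @export
transient_run <- function(network, state, scen, forcings, lrp,
                          params = network$params, natural = NULL,
                          load_scale = NULL) {
  if (scen$dams == "on" && is.null(natural)) {
    stop("managed run requires the preceding natural-flow result", call. = FALSE)
  }
  fz <- freeze_forcings(forcings, scen$fixed_factors)
  loads_obj <- terrestrial_loads(fz, network, lrp)
  ny <- length(fz$years)
  E <- network$n_elements
  emis <- matrix(0, ny, E)
  n2 <- matrix(0, ny, E)
  resid <- c(water = 0, n = 0, eq1 = 0)
  for (y in seq_len(ny)) {
    state <- set_dam_year(network, state, fz$years[y],
                          natural_flow = scen$dams == "off")
    yf <- year_forcing(fz, loads_obj, y, params, load_scale)
    out <- run_year(network, state, yf, params)
    state <- out$state
    emis[y, ] <- out$annual$efflux
    n2[y, ] <- out$annual$n2
    resid <- pmax(resid, c(out$annual$max_resid_water,
                           out$annual$max_resid_n, out$annual$max_resid_eq1))
  }
  structure(list(
    scenario = scen, years = fz$years, emissions = emis, n2 = n2,
    kind = network$kind, country = network$country[network$cell_of],
    cell_of = network$cell_of,
    ag_additions = loads_obj$ag_additions,
    residuals = resid, final_state = state
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  tot <- annual_series(x, "inland")
  cat("scenario_result", x$scenario$scenario_id, "(dams", x$scenario$dams,
      if (length(x$scenario$fixed_factors))
        paste0(", fixed: ", paste(x$scenario$fixed_factors, collapse = "+")),
      ")\n  inland-water N2O,", min(x$years), "-", max(x$years), ": ",
      signif(tot[1], 3), "->", signif(tot[length(tot)], 3), "Gg N/yr\n")
  invisible(x)
}

KIND_GROUPS <- list(
  river = c("subnetwork", "main"),
  lake = c("lake_small", "lake_large"),
  reservoir = c("reservoir_small", "reservoir_large"),
  lentic = c("lake_small", "lake_large", "reservoir_small", "reservoir_large"),
  small_lentic = c("lake_small", "reservoir_small"),
  large_lentic = c("lake_large", "reservoir_large"),
  inland = c("subnetwork", "main", "lake_small", "lake_large",
             "reservoir_small", "reservoir_large")
)

#' Annual emission series from a scenario result
#'
#' @param result a `scenario_result`.
#' @param which one of `"inland"`, `"lentic"`, `"river"`, `"lake"`,
#'   `"reservoir"`, `"small_lentic"`, `"large_lentic"`, or an exact element
#'   kind (e.g. `"lake_small"`).
#' @return numeric vector (one value per year), Gg N yr^-1.
#' @export
annual_series <- function(result, which = "lentic") {
  kinds <- KIND_GROUPS[[which]]
  if (is.null(kinds)) kinds <- which
  sel <- result$kind %in% kinds
  if (!any(sel)) return(rep(0, length(result$years)))
  rowSums(result$emissions[, sel, drop = FALSE]) / 1e9
}

#' Decadal mean and spread of an annual series
#'
#' Decades are labelled by their starting year ([X0, X9]; "the 2010s" is
#' 2010-2019). The reported uncertainty is the standard deviation of the
#' annual values within the decade.
#'
#' @param series annual values.
#' @param years matching calendar years.
#' @return data.frame with `decade`, `mean`, `sd`, `n`.
#' @export
decadal_stats <- function(series, years) {
  dec <- floor(years / 10) * 10
  agg <- function(f) tapply(series, dec, f)
  data.frame(decade = as.integer(names(agg(mean))),
             mean = as.numeric(agg(mean)), sd = as.numeric(agg(stats::sd)),
             n = as.integer(agg(length)), row.names = NULL)
}

decadal_mean_of <- function(result, decade, which = "lentic") {
  s <- annual_series(result, which)
  d <- decadal_stats(s, result$years)
  i <- match(decade, d$decade)
  if (is.na(i)) stop("decade ", decade, " not in result", call. = FALSE)
  d$mean[i]
}

#' Factorial attribution of emission changes
#'
#' For each factor f, the absolute contribution over the period is
#' `deltaS1 - deltaS_f`, where delta is the change of the decadal-mean
#' emission between the two decades; the relative contribution is
#' `contribution / |net change of S1| * 100` (sign preserved — CO2
#' suppression shows up negative). The interaction residual
#' `deltaS1 - sum(contributions)` is reported separately, so the closure
#' `sum(contributions) + interaction = deltaS1` is exact. A second
#' normalisation over the sum of absolute contributions is also emitted.
#'
#' @param results named list of `scenario_result`s: the all-combined S1
#'   plus one single-factor run per factor, all branched from the same
#'   spin-up state.
#' @param period length-2 vector of decade labels, e.g. `c(1850, 2010)`.
#' @param which emission aggregate to attribute (see [annual_series()]).
#' @return data.frame (one row per factor) with `factor`, `absolute`
#'   (Gg N yr^-1), `relative_pct`, `relative_pct_norm`; attributes
#'   `net_change` and `interaction`.
#' @export
attribute <- function(results, period, which = "lentic") {
  is_s1 <- vapply(results, function(r)
    length(r$scenario$fixed_factors) == 0, logical(1))
  if (!any(is_s1)) stop("results must include the all-transient S1 run", call. = FALSE)
  s1 <- results[[base::which(is_s1)[1]]]
  d1 <- decadal_mean_of(s1, period[2], which) - decadal_mean_of(s1, period[1], which)
  rows <- lapply(results, function(r) {
    if (length(r$scenario$fixed_factors) != 1) return(NULL)
    dr <- decadal_mean_of(r, period[2], which) - decadal_mean_of(r, period[1], which)
    data.frame(factor = r$scenario$fixed_factors, absolute = d1 - dr)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || !nrow(out)) stop("no single-factor runs supplied", call. = FALSE)
  out$relative_pct <- if (d1 != 0) out$absolute / abs(d1) * 100 else 0
  tot_abs <- sum(abs(out$absolute))
  out$relative_pct_norm <- if (tot_abs > 0) out$absolute / tot_abs * 100 else 0
  attr(out, "net_change") <- d1
  attr(out, "interaction") <- d1 - sum(out$absolute)
  rownames(out) <- NULL
  out
}

#' Load-perturbation uncertainty ensemble
#'
#' Runs the two bracketing members — every species load scaled down
#' (all-low) and up (all-high) by its perturbation — around the central
#' run, and reports min/centre/max decadal emissions.
#'
#' @param network,state,forcings,lrp,params,natural as in [transient_run()].
#' @param center optional precomputed central `scenario_result` (S1); run
#'   if NULL.
#' @param perturbations named fractional perturbations (defaults
#'   no3 22%, nh4 50%, don 37%, pon 26%).
#' @param which emission aggregate for the summary table.
#' @return list with the three `scenario_result`s (`low`, `center`,
#'   `high`) and `decadal` — data.frame decade / low / center / high
#'   (Gg N yr^-1).
#' @export
uncertainty_ensemble <- function(network, state, forcings, lrp,
                                 params = network$params, natural,
                                 center = NULL,
                                 perturbations = c(no3 = 0.22, nh4 = 0.50,
                                                   don = 0.37, pon = 0.26),
                                 which = "lentic") {
  s1 <- scenario("S1")
  if (is.null(center)) {
    center <- transient_run(network, state, s1, forcings, lrp, params, natural)
  }
  lo <- transient_run(network, state, s1, forcings, lrp, params, natural,
                      load_scale = as.list(1 - perturbations))
  hi <- transient_run(network, state, s1, forcings, lrp, params, natural,
                      load_scale = as.list(1 + perturbations))
  dc <- decadal_stats(annual_series(center, which), center$years)
  dl <- decadal_stats(annual_series(lo, which), lo$years)
  dh <- decadal_stats(annual_series(hi, which), hi$years)
  list(low = lo, center = center, high = hi,
       decadal = data.frame(decade = dc$decade, low = dl$mean,
                            center = dc$mean, high = dh$mean))
}

#' Run the full simulation protocol on a world
#'
#' Equilibrium at first-year forcing, 30-year randomised-1850s spin-up,
#' the natural-flow transient, the dam-managed all-combined run (S1), and
#' the five factorial experiments (S2-S6), all factorial runs branching
#' from the common post-spin-up state. Returns every result plus a
#' manifest from which the run is bit-identically reconstructible.
#'
#' @param world a fixture from [reference_fixture()] (or a list with
#'   `network`, `forcings`, `lrp`, `seed`).
#' @param params parameter list.
#' @param seed protocol seed (spin-up year draw).
#' @param tol,max_years equilibrium controls.
#' @param scenarios scenario list (default [default_scenarios()]).
#' @return list with `equilibrium`, `spinup`, `natural`, `results` (named
#'   `scenario_result`s), and `manifest`.
#' @export
run_protocol <- function(world, params = world$network$params, seed = 7L,
                         tol = 1e-4, max_years = 200,
                         scenarios = default_scenarios()) {
  net <- world$network
  loads0 <- terrestrial_loads(world$forcings, net, world$lrp)
  eq <- equilibrium_run(net, world$forcings, loads0, params,
                        tol = tol, max_years = max_years)
  sp <- spinup_run(net, eq$state, world$forcings, loads0, params,
                   years = 30, seed = seed)
  natural <- transient_run(net, sp$state,
                           scenario("S1-natural", dams = "off"),
                           world$forcings, world$lrp, params)
  results <- list()
  for (nm in names(scenarios)) {
    results[[nm]] <- transient_run(net, sp$state, scenarios[[nm]],
                                   world$forcings, world$lrp, params,
                                   natural = natural)
  }
  manifest <- list(
    package = "inlandn2o",
    version = as.character(utils::packageVersion("inlandn2o")),
    world_seed = world$seed, forcing_seed = world$forcings$seed,
    dims = world$dims,
    protocol_seed = seed, equilibrium = list(tol = tol, max_years = max_years),
    params = params, lrp = unclass(world$lrp),
    trend = world$forcings$trend,
    scenarios = lapply(scenarios, unclass)
  )
  list(equilibrium = eq, spinup = sp, natural = natural, results = results,
       manifest = manifest)
}
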
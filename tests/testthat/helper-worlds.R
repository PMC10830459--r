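# Shared fixture builders. Everything is generated in code; expensive
# objects are memoised per test run.

.world_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.world_cache[[key]])) .world_cache[[key]] <- force(expr)
  .world_cache[[key]]
}

# explicit two-cell chain A -> B -> outlet, optionally with one lake in B
chain_tables <- function(lake_in_b = TRUE, lake_small = TRUE) {
  cells <- data.frame(cell_id = c("A", "B"), lat = c(45.5, 45),
                      lon = c(0, 0), downstream_id = c("B", -1),
                      country_code = c(1, 1))
  reaches <- rbind(
    data.frame(cell_id = c("A", "B"), corridor = "subnetwork",
               length_m = 1e5, width_m = 5, slope = 1e-3),
    data.frame(cell_id = c("A", "B"), corridor = "main",
               length_m = 5e4, width_m = 20, slope = 5e-4))
  bodies <- NULL
  if (lake_in_b) {
    ca <- cell_area_from_latitude(45, 0.5)
    bodies <- data.frame(body_id = "L1", cell_id = "B", kind = "lake",
                         area_m2 = 1e7, volume_m3 = 5e7, depth_m = 5,
                         residence_days = 100,
                         upstream_m2 = if (lake_small) 0.4 * ca else 2 * ca,
                         built_year = NA_real_)
  }
  list(cells = cells, reaches = reaches, bodies = bodies)
}

# one cell holding a single large lake in-line on the main channel
single_body_tables <- function(tau = 20, depth = 5, area = 1e7,
                               kind = "lake", built_year = NA_real_) {
  ca <- cell_area_from_latitude(45, 0.5)
  list(
    cells = data.frame(cell_id = 0, lat = 45, lon = 0, downstream_id = -1,
                       country_code = 1),
    reaches = rbind(
      data.frame(cell_id = 0, corridor = "subnetwork", length_m = 1e5,
                 width_m = 5, slope = 1e-3),
      data.frame(cell_id = 0, corridor = "main", length_m = 5e4,
                 width_m = 20, slope = 5e-4)),
    bodies = data.frame(body_id = "B1", cell_id = 0, kind = kind,
                        area_m2 = area, volume_m3 = area * depth,
                        depth_m = depth, residence_days = tau,
                        upstream_m2 = 2 * ca, built_year = built_year))
}

build_world <- function(tabs, params = default_params()) {
  build_network(tabs$cells, tabs$reaches, tabs$bodies, params)
}

# a quiet constant-forcing year bundle for direct run_year calls
const_year <- function(n_cells, tair = 15, precip_m = 0.002, wind = 3,
                       x_atm = 300, loads = NULL, days = 365) {
  list(tair = rep(tair, days), precip_m = rep(precip_m, days),
       w = rep(1 / days, days), wind = wind, x_atm = x_atm, loads = loads)
}

# small deterministic-climate world reused by protocol tests: 5 x 5 grid,
# 80 years, strong warming as the only active load driver unless stated
tiny_world <- function(key = "default", lrp = load_response_params(),
                       trend = list(), years = 1850:1879, seed = 11) {
  memo(paste0("tiny_", key), {
    reference_fixture(seed = seed, n_side = 5, n_lakes = 3, n_reservoirs = 2,
                      years = years, trend = trend, lrp = lrp)
  })
}

run_years_const <- function(net, st, yf, n, params = net$params) {
  ann <- NULL
  for (i in seq_len(n)) {
    out <- run_year(net, st, yf, params)
    st <- out$state; ann <- out$annual
  }
  list(state = st, annual = ann)
}
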
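#' Area of a spherical grid cell centred at a latitude
#'
#' Area of the spherical quadrangle of width `resolution` degrees in both
#' longitude and latitude, centred at `latitude`, on a sphere of radius
#' 6,371,000 m: \eqn{A = R^2 \Delta\lambda (\sin\phi_2 - \sin\phi_1)}.
#'
#' @param latitude cell-centre latitude in degrees (vectorised).
#' @param resolution grid resolution in degrees (> 0).
#' @return cell area in m^2.
#' @export
#' @examples
#' cell_area_from_latitude(0, 0.5)   # ~3.09e9 m^2 at the equator
cell_area_from_latitude <- function(latitude, resolution = 0.5) {
  if (any(abs(latitude) > 90)) stop("latitude must lie in [-90, 90]", call. = FALSE)
  if (resolution <= 0) stop("resolution must be > 0", call. = FALSE)
  r_earth <- 6371000
  half <- resolution / 2
  phi1 <- pmax(latitude - half, -90) * pi / 180
  phi2 <- pmin(latitude + half, 90) * pi / 180
  dlam <- resolution * pi / 180
  r_earth^2 * dlam * (sin(phi2) - sin(phi1))
}

#' Classify a lentic body as small or large
#'
#' A lake or reservoir whose upstream catchment area exceeds the grid-cell
#' area is "large" and sits on the main channel; otherwise it is "small"
#' and is fed by intercepted hillslope flow ahead of the subnetwork. Ties
#' (upstream area exactly equal to the cell area) classify as small: the
#' rule is a strict "greater than".
#'
#' @param upstream_area upstream catchment area, m^2 (vectorised).
#' @param cell_area grid-cell area, m^2.
#' @return character vector, `"small"` or `"large"`.
#' @export
classify_lentic <- function(upstream_area, cell_area) {
  if (any(upstream_area < 0) || any(cell_area < 0)) {
    stop("areas must be non-negative", call. = FALSE)
  }
  ifelse(upstream_area > cell_area, "large", "small")
}

#' Hillslope interception fraction of a small lentic body
#'
#' The share of a cell's hillslope runoff (and its nitrogen load) that is
#' routed through a small body before the subnetwork:
#' `min(upstream_area / cell_area, 1)`. Large bodies sit in-line on the
#' main channel and receive the full upstream flow, so calling this on a
#' large-class body is a usage error.
#'
#' @param body one row of a bodies table (list or single-row data.frame)
#'   with fields `upstream_m2` and `size_class`.
#' @param cell one row of a cells table with field `lat`.
#' @param resolution_deg grid resolution used for the cell area.
#' @return interception fraction in [0, 1].
#' @export
interception_fraction <- function(body, cell, resolution_deg = 0.5) {
  if (!identical(as.character(body$size_class), "small")) {
    stop("interception_fraction applies to small-class bodies only", call. = FALSE)
  }
  ca <- cell_area_from_latitude(cell$lat, resolution_deg)
  min(body$upstream_m2 / ca, 1)
}

# Kahn topological sort on the cell drainage forest. Returns indices in
# processing order (headwaters first); on a cycle, errors naming the cells
# left unresolved (exactly the cycle members and their downstream captives).
topo_sort_cells <- function(cell_id, down_idx) {
  n <- length(cell_id)
  indeg <- tabulate(down_idx[down_idx > 0], nbins = n)
  queue <- which(indeg == 0)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    order <- c(order, v)
    d <- down_idx[[v]]
    if (d > 0) {
      indeg[[d]] <- indeg[[d]] - 1L
      if (indeg[[d]] == 0L) queue <- c(queue, d)
    }
  }
  if (length(order) < n) {
    bad <- setdiff(seq_len(n), order)
    stop("topology error: cycle detected involving cell(s): ",
         paste(cell_id[bad], collapse = ", "), call. = FALSE)
  }
  order
}

validate_network_tables <- function(cells, reaches, bodies) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop("schema error in ", what, ": missing column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }
  need(cells,   c("cell_id", "lat", "lon", "downstream_id", "country_code"), "cells")
  need(reaches, c("cell_id", "corridor", "length_m", "width_m", "slope"), "reaches")
  need(bodies,  c("body_id", "cell_id", "kind", "area_m2", "volume_m3", "depth_m",
                  "residence_days", "upstream_m2", "built_year"), "bodies")
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell_id in cells", call. = FALSE)
  if (nrow(bodies) && anyDuplicated(bodies$body_id)) stop("duplicate body_id in bodies", call. = FALSE)
  if (any(reaches$length_m <= 0) || any(reaches$width_m <= 0)) {
    stop("reach length and width must be > 0", call. = FALSE)
  }
  if (any(reaches$slope < 0)) stop("reach slope must be >= 0", call. = FALSE)
  if (!all(reaches$corridor %in% c("subnetwork", "main"))) {
    stop("reach corridor must be 'subnetwork' or 'main'", call. = FALSE)
  }
  if (nrow(bodies)) {
    if (!all(bodies$kind %in% c("lake", "reservoir"))) {
      stop("body kind must be 'lake' or 'reservoir'", call. = FALSE)
    }
    if (any(bodies$residence_days <= 0)) stop("residence_days must be > 0", call. = FALSE)
    if (any(bodies$area_m2 <= 0) || any(bodies$volume_m3 <= 0) || any(bodies$depth_m <= 0)) {
      stop("body area, volume and depth must be > 0", call. = FALSE)
    }
    if (any(bodies$upstream_m2 < 0)) stop("upstream_m2 must be >= 0", call. = FALSE)
    rel <- abs(bodies$volume_m3 - bodies$area_m2 * bodies$depth_m) /
      (bodies$area_m2 * bodies$depth_m)
    if (any(rel > 0.10)) {
      stop("body volume inconsistent with area x depth (>10%): ",
           paste(bodies$body_id[rel > 0.10], collapse = ", "), call. = FALSE)
    }
    res <- bodies$kind == "reservoir"
    if (any(res & !is.finite(bodies$built_year))) {
      stop("reservoirs must carry a construction year", call. = FALSE)
    }
    if (any(!res & is.finite(bodies$built_year))) {
      stop("lakes must not carry a construction year", call. = FALSE)
    }
    orphan <- setdiff(bodies$cell_id, cells$cell_id)
    if (length(orphan)) stop("reference error: bodies in unknown cell(s): ",
                             paste(orphan, collapse = ", "), call. = FALSE)
  }
  orphan <- setdiff(reaches$cell_id, cells$cell_id)
  if (length(orphan)) stop("reference error: reaches in unknown cell(s): ",
                           paste(orphan, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Build and validate a routing network
#'
#' Assembles the watershed graph from the three input tables, enforces
#' acyclicity (Kahn's algorithm; any cycle is reported by name), classifies
#' every lentic body against the configured grid-cell area, and compiles
#' the per-element structures the daily engine uses: one subnetwork and one
#' main-channel element per cell plus one element per body, destination
#' links, sequential hillslope interception shares for co-located small
#' bodies, and per-day outflow fractions from channel celerity or
#' residence time.
#'
#' Outlet cells carry a `downstream_id` of -1 (or NA). Within a cell,
#' hillslope runoff splits across small bodies in descending order of
#' upstream area (each takes `min(upstream/cell_area, 1)` of what remains)
#' with the residual feeding the subnetwork reach; subnetwork and
#' small-body outflow drain to the main channel; large bodies sit in-line
#' on the main channel in descending upstream-area order.
#'
#' @param cells data.frame: `cell_id, lat, lon, downstream_id, country_code`.
#' @param reaches data.frame: `cell_id, corridor, length_m, width_m, slope`
#'   (one row per cell per corridor).
#' @param bodies data.frame: `body_id, cell_id, kind, area_m2, volume_m3,
#'   depth_m, residence_days, upstream_m2, built_year` (NA for lakes).
#' @param params parameter list from [default_params()].
#' @return an object of class `routing_network`.
#' @export
build_network <- function(cells, reaches, bodies = NULL, params = default_params()) {
  cells <- as.data.frame(cells); reaches <- as.data.frame(reaches)
  if (is.null(bodies)) {
    bodies <- data.frame(body_id = character(0), cell_id = character(0),
                         kind = character(0), area_m2 = numeric(0),
                         volume_m3 = numeric(0), depth_m = numeric(0),
                         residence_days = numeric(0), upstream_m2 = numeric(0),
                         built_year = numeric(0))
  }
  bodies <- as.data.frame(bodies)
  bodies$built_year <- suppressWarnings(as.numeric(bodies$built_year))
  validate_network_tables(cells, reaches, bodies)

  n <- nrow(cells)
  idx_of <- stats::setNames(seq_len(n), as.character(cells$cell_id))
  down_raw <- cells$downstream_id
  is_outlet <- is.na(down_raw) | down_raw == -1 | down_raw == "-1"
  down_idx <- integer(n)
  down_idx[is_outlet] <- 0L
  if (any(!is_outlet)) {
    m <- idx_of[as.character(down_raw[!is_outlet])]
    if (anyNA(m)) {
      bad <- as.character(down_raw[!is_outlet])[is.na(m)]
      stop("reference error: dangling downstream id(s): ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
    down_idx[!is_outlet] <- as.integer(m)
  }
  if (any(down_idx == seq_len(n))) {
    stop("topology error: cycle detected involving cell(s): ",
         paste(cells$cell_id[down_idx == seq_len(n)], collapse = ", "), call. = FALSE)
  }
  order <- topo_sort_cells(cells$cell_id, down_idx)

  cell_area <- cell_area_from_latitude(cells$lat, params$resolution_deg)

  # reach lookup: one subnetwork + one main row per cell
  reach_row <- function(corr) {
    r <- reaches[reaches$corridor == corr, , drop = FALSE]
    i <- match(cells$cell_id, r$cell_id)
    if (anyNA(i)) stop("schema error: every cell needs a '", corr, "' reach", call. = FALSE)
    r[i, , drop = FALSE]
  }
  sub_r <- reach_row("subnetwork"); main_r <- reach_row("main")

  nb <- nrow(bodies)
  if (nb) {
    bcell <- as.integer(idx_of[as.character(bodies$cell_id)])
    bodies$size_class <- classify_lentic(bodies$upstream_m2, cell_area[bcell])
  } else {
    bcell <- integer(0); bodies$size_class <- character(0)
  }

  E <- 2L * n + nb
  e_sub <- seq_len(n); e_main <- n + seq_len(n); e_body <- if (nb) 2L * n + seq_len(nb) else integer(0)

  kind <- c(rep("subnetwork", n), rep("main", n),
            if (nb) paste0(bodies$kind, "_", bodies$size_class))
  cell_of <- c(seq_len(n), seq_len(n), bcell)
  surf <- c(sub_r$length_m * sub_r$width_m, main_r$length_m * main_r$width_m,
            bodies$area_m2)
  slope <- c(sub_r$slope, main_r$slope, rep(0, nb))
  length_m <- c(sub_r$length_m, main_r$length_m, rep(NA_real_, nb))
  is_lentic <- c(rep(FALSE, 2L * n), rep(TRUE, nb))
  is_res <- c(rep(FALSE, 2L * n), if (nb) bodies$kind == "reservoir" else logical(0))
  built <- c(rep(NA_real_, 2L * n), bodies$built_year)
  residence <- c(rep(NA_real_, 2L * n), bodies$residence_days)

  dt <- params$dt_days
  travel_d <- length_m / (params$celerity_ms * 86400)
  out_frac <- numeric(E)
  out_frac[c(e_sub, e_main)] <- pmin(dt / pmax(travel_d[c(e_sub, e_main)], dt), 1)
  if (nb) out_frac[e_body] <- pmin(dt / residence[e_body], 1)

  # hillslope splitting and destinations
  hs_share <- numeric(E)
  dest <- integer(E)
  dest[e_sub] <- e_main
  for (ci in seq_len(n)) {
    bi <- which(bcell == ci)
    small <- bi[bodies$size_class[bi] == "small"]
    large <- bi[bodies$size_class[bi] == "large"]
    remaining <- 1.0
    if (length(small)) {
      small <- small[order(-bodies$upstream_m2[small])]
      for (b in small) {
        f <- min(bodies$upstream_m2[[b]] / cell_area[[ci]], 1)
        hs_share[[2L * n + b]] <- remaining * f
        remaining <- remaining * (1 - f)
        dest[[2L * n + b]] <- e_main[[ci]]
      }
    }
    hs_share[[e_sub[[ci]]]] <- remaining
    down_main <- if (down_idx[[ci]] > 0) e_main[[down_idx[[ci]]]] else 0L
    if (length(large)) {
      large <- large[order(-bodies$upstream_m2[large])]
      chain <- 2L * n + large
      dest[[e_main[[ci]]]] <- chain[[1]]
      if (length(chain) > 1) {
        for (k in seq_len(length(chain) - 1)) dest[[chain[[k]]]] <- chain[[k + 1]]
      }
      dest[[chain[[length(chain)]]]] <- down_main
    } else {
      dest[[e_main[[ci]]]] <- down_main
    }
  }

  nz <- which(dest > 0)
  transfer <- Matrix::sparseMatrix(i = dest[nz], j = nz, x = 1, dims = c(E, E))
  outlet_e <- which(dest == 0L)

  structure(list(
    cells = cells, reaches = reaches, bodies = bodies,
    n_cells = n, n_bodies = nb, n_elements = E,
    order = order, down_idx = down_idx, cell_area = cell_area,
    e_sub = e_sub, e_main = e_main, e_body = e_body,
    kind = kind, cell_of = cell_of, surf = surf, slope = slope,
    length_m = length_m, is_lentic = is_lentic, is_res = is_res,
    built_year = built, residence = residence, out_frac = out_frac,
    hs_share = hs_share, dest = dest, transfer = transfer,
    outlet_e = outlet_e, lent_num = as.numeric(is_lentic),
    sqrt_slope = sqrt(slope),
    country = as.character(cells$country_code),
    params = params
  ), class = "routing_network")
}

#' @export
print.routing_network <- function(x, ...) {
  cat("routing_network:", x$n_cells, "cells,", x$n_bodies, "lentic bodies (",
      sum(x$kind %in% c("lake_small", "reservoir_small")), "small /",
      sum(x$kind %in% c("lake_large", "reservoir_large")), "large ),",
      sum(x$down_idx == 0), "outlet(s)\n")
  invisible(x)
}
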
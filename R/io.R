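# Readers/writers: strict-schema CSV tables, the JSON run manifest (every
# run is reconstructible from it alone), long-format gridded output with a
# JSON sidecar header (the environment provides no NetCDF library; the
# (time, cell) dimension layout and unit metadata follow the same
# convention), and the documented rename map that adapts HydroLAKES/GRanD
# style attribute extracts onto the bodies schema.

REQUIRED_COLS <- list(
  cells = c("cell_id", "lat", "lon", "downstream_id", "country_code"),
  reaches = c("cell_id", "corridor", "length_m", "width_m", "slope"),
  bodies = c("body_id", "cell_id", "kind", "area_m2", "volume_m3", "depth_m",
             "residence_days", "upstream_m2", "built_year"),
  countries = c("cell_id", "country_code")
)

read_checked_csv <- function(path, what) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(REQUIRED_COLS[[what]], names(df))
  if (length(miss)) stop("schema error in ", basename(path),
                         ": missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df
}

#' Read and validate the network input tables
#'
#' Reads `cells.csv`, `reaches.csv` and (if present) `bodies.csv` and
#' `countries.csv` from a directory, enforces the schemas (missing columns
#' are named in the error), and returns the validated tables. A separate
#' `countries.csv` overrides the country codes carried in `cells.csv`.
#'
#' @param dir directory holding the CSV tables.
#' @return list of data.frames `cells`, `reaches`, `bodies`.
#' @export
read_tables <- function(dir) {
  cells <- read_checked_csv(file.path(dir, "cells.csv"), "cells")
  reaches <- read_checked_csv(file.path(dir, "reaches.csv"), "reaches")
  bodies <- NULL
  bp <- file.path(dir, "bodies.csv")
  if (file.exists(bp)) bodies <- read_checked_csv(bp, "bodies")
  cp <- file.path(dir, "countries.csv")
  if (file.exists(cp)) {
    cmap <- read_checked_csv(cp, "countries")
    i <- match(cells$cell_id, cmap$cell_id)
    if (anyNA(i)) stop("countries.csv does not cover every cell", call. = FALSE)
    cells$country_code <- cmap$country_code[i]
  }
  list(cells = cells, reaches = reaches, bodies = bodies)
}

#' Write network tables to a directory
#' @param tables list with `cells`, `reaches`, `bodies`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tables$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(tables$reaches, file.path(dir, "reaches.csv"), row.names = FALSE)
  if (!is.null(tables$bodies)) {
    utils::write.csv(tables$bodies, file.path(dir, "bodies.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Rename map from HydroLAKES/GRanD-style attributes to the bodies schema
#'
#' `cols` maps source column names onto schema names; `scale` converts the
#' source units (km^2 and million m^3) to m^2/m^3. Apply with
#' [adapt_lentic_table()].
#' @return list with `cols` and `scale`.
#' @export
hydrolakes_rename_map <- function() {
  list(cols = c(Hylak_id = "body_id", Grid_id = "cell_id", Lake_type = "kind",
                Lake_area = "area_m2", Vol_total = "volume_m3",
                Depth_avg = "depth_m", Res_time = "residence_days",
                Wshd_area = "upstream_m2", Year = "built_year"),
       scale = c(area_m2 = 1e6, volume_m3 = 1e6, upstream_m2 = 1e6))
}

#' Adapt an attribute extract onto the bodies schema
#'
#' @param df data.frame in the source vocabulary.
#' @param map a rename map (see [hydrolakes_rename_map()]).
#' @return data.frame in the bodies schema.
#' @export
adapt_lentic_table <- function(df, map = hydrolakes_rename_map()) {
  hit <- names(map$cols) %in% names(df)
  if (!all(hit)) stop("extract missing column(s): ",
                      paste(names(map$cols)[!hit], collapse = ", "), call. = FALSE)
  out <- df[names(map$cols)]
  names(out) <- unname(map$cols)
  for (cn in names(map$scale)) out[[cn]] <- out[[cn]] * map$scale[[cn]]
  if (!is.character(out$kind)) {
    out$kind <- ifelse(out$kind %in% c(2, "2", "Reservoir", "reservoir"),
                       "reservoir", "lake")
  }
  out$built_year[out$kind == "lake"] <- NA_real_
  out
}

#' Write a (time, cell) gridded series as CSV plus a JSON sidecar header
#'
#' Long format (`time`, `cell_id`, `value`) with a `<path>.json` header
#' carrying dimension sizes, units and provenance — a plain-text stand-in
#' for a self-describing array file.
#'
#' @param mat matrix, rows = time, columns = cells.
#' @param times time labels (e.g. years).
#' @param cell_ids cell labels.
#' @param path output CSV path.
#' @param units unit string stored in the header.
#' @param name variable name stored in the header.
#' @return `path`, invisibly.
#' @export
write_gridded <- function(mat, times, cell_ids, path, units = "g N yr-1",
                          name = "n2o_efflux") {
  stopifnot(nrow(mat) == length(times), ncol(mat) == length(cell_ids))
  df <- data.frame(time = rep(times, times = ncol(mat)),
                   cell_id = rep(cell_ids, each = nrow(mat)),
                   value = as.vector(mat))
  utils::write.csv(df, path, row.names = FALSE)
  hdr <- list(variable = name, units = units,
              dims = list(time = length(times), cell = length(cell_ids)),
              convention = "long CSV (time, cell) + JSON header",
              created_by = paste0("inlandn2o ",
                                  as.character(utils::packageVersion("inlandn2o"))))
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a gridded CSV back into a matrix
#' @param path CSV written by [write_gridded()].
#' @return matrix with times as rownames and cell ids as colnames.
#' @export
read_gridded <- function(path) {
  df <- utils::read.csv(path)
  times <- unique(df$time); cells <- unique(df$cell_id)
  matrix(df$value, length(times), length(cells),
         dimnames = list(times, cells))
}

#' Write / read a run manifest
#'
#' The manifest (JSON) carries every parameter, trend coefficient and seed
#' of a run: a run is reconstructible from its manifest alone.
#' @param manifest named list.
#' @param path JSON path.
#' @return `path` / the manifest list.
#' @export
write_manifest <- function(manifest, path) {
  # jsonlite drops names on atomic vectors; promote them to objects
  keep_names <- function(x) {
    if (is.list(x)) lapply(x, keep_names)
    else if (!is.null(names(x)) && length(x) > 1) as.list(x)
    else x
  }
  jsonlite::write_json(keep_names(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Rebuild a world from a manifest
#'
#' Regenerates the synthetic world (tables, network, forcings, load
#' parameters) bit-identically from the seeds and parameters recorded in a
#' run manifest.
#' @param manifest list from [read_manifest()].
#' @return a world list as from [reference_fixture()].
#' @export
world_from_manifest <- function(manifest) {
  params <- default_params(as.list(manifest$params))
  lrp_in <- manifest$lrp
  lrp_in$base <- unlist(lrp_in$base)
  lrp_in$leach_split <- unlist(lrp_in$leach_split)
  lrp <- load_response_params(lrp_in)
  dims <- manifest$dims
  if (is.null(dims)) dims <- list(n_side = 20, n_lakes = 8, n_reservoirs = 4,
                                  year_min = 1850, year_max = 2019)
  w <- reference_fixture(seed = manifest$world_seed, params = params,
                         n_side = dims$n_side, n_lakes = dims$n_lakes,
                         n_reservoirs = dims$n_reservoirs,
                         years = dims$year_min:dims$year_max,
                         trend = as.list(manifest$trend), lrp = lrp)
  if (!identical(w$forcings$seed, manifest$forcing_seed)) {
    w$forcings <- generate_forcings(years = dims$year_min:dims$year_max,
                                    trend = as.list(manifest$trend),
                                    seed = manifest$forcing_seed)
  }
  w
}

#' Write the standard outputs of a protocol run
#'
#' Annual and decadal emission series per scenario and aggregate, the
#' country-level EF table (when S1 and S6 are present), per-cell gridded
#' S1 emissions, and the manifest.
#'
#' @param protocol output of [run_protocol()].
#' @param network the `routing_network` used.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(protocol, network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  groups <- c("inland", "lentic", "river", "lake", "reservoir",
              "small_lentic", "large_lentic")
  ann <- list(); dec <- list()
  for (nm in names(protocol$results)) {
    r <- protocol$results[[nm]]
    for (g in groups) {
      s <- annual_series(r, g)
      ann[[length(ann) + 1]] <- data.frame(scenario = nm, group = g,
                                           year = r$years, emissions_GgN_yr = s)
      d <- decadal_stats(s, r$years)
      dec[[length(dec) + 1]] <- data.frame(scenario = nm, group = g, d)
    }
  }
  utils::write.csv(do.call(rbind, ann), file.path(dir, "annual_emissions.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, dec), file.path(dir, "decadal_emissions.csv"),
                   row.names = FALSE)
  if (all(c("S1", "S6") %in% names(protocol$results))) {
    utils::write.csv(ef_by_country(protocol$results$S1, protocol$results$S6,
                                   network),
                     file.path(dir, "ef_by_country.csv"), row.names = FALSE)
  }
  s1 <- protocol$results[[1]]
  cellmat <- t(rowsum(t(s1$emissions), network$cell_of))
  write_gridded(cellmat, s1$years, network$cells$cell_id,
                file.path(dir, "s1_cell_emissions.csv"))
  write_manifest(protocol$manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}
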
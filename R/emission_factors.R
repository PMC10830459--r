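#' Agricultural emission factor for inland-water N2O
#'
#' `EF_Ag = (S1 - S6) / additions * 100%`: the agriculture-induced
#' inland-water N2O emission (the difference between the all-combined run
#' and the run holding agricultural N at its first-year value) as a
#' percentage of agricultural N additions (fertilizer + manure) over the
#' same region and decade. A negative raw EF (unsaturated N2O in the
#' pre-fertilizer era, or weakly agricultural regions) is clamped to zero;
#' zero additions yield EF 0 with a `no_agriculture` flag.
#'
#' @param s1_emissions,s6_emissions emissions, Gg N yr^-1 (vectorised over
#'   regions/decades).
#' @param additions agricultural N additions, Gg N yr^-1 (>= 0).
#' @param region,decade optional labels carried through.
#' @return data.frame (`EFRecord`) with `region`, `decade`, `n2o_ag_GgN`,
#'   `additions_GgN`, `ef_pct`, `clamped`, `no_agriculture`.
#' @export
ef_ag <- function(s1_emissions, s6_emissions, additions,
                  region = "GLOBAL", decade = NA_integer_) {
  if (any(additions < 0)) stop("additions must be >= 0", call. = FALSE)
  n2o_ag <- s1_emissions - s6_emissions
  raw <- ifelse(additions > 0, n2o_ag / additions * 100, 0)
  data.frame(region = region, decade = decade,
             n2o_ag_GgN = n2o_ag, additions_GgN = additions,
             ef_pct = pmax(raw, 0),
             clamped = raw < 0,
             no_agriculture = additions == 0)
}

#' Aggregate per-cell emissions by country
#'
#' Sums per-cell values within country codes; code 0 (unclaimed/ocean) is
#' excluded from the per-country rows but `GLOBAL` always sums every
#' claimed cell, so the claimed-country rows partition the global total
#' exactly.
#'
#' @param values per-cell annual values (numeric, same unit throughout).
#' @param country_code per-cell country codes (0 = unclaimed).
#' @return data.frame with `region` (country codes as character, plus
#'   `"GLOBAL"`) and `value`.
#' @export
aggregate_by_country <- function(values, country_code) {
  stopifnot(length(values) == length(country_code))
  keep <- country_code != 0
  v <- tapply(values[keep], as.character(country_code[keep]), sum)
  data.frame(region = c(names(v), "GLOBAL"),
             value = c(as.numeric(v), sum(values[keep])),
             row.names = NULL)
}

#' Convert an N2O-N flux to CO2 equivalents
#'
#' `Tg CO2e yr^-1 = Gg N yr^-1 * (44/28) * GWP / 1000`: mass of N2O from
#' its nitrogen content, times the 100-year global warming potential
#' (default 273), Gg to Tg.
#'
#' @param flux_gg_n flux, Gg N2O-N yr^-1 (>= 0, vectorised).
#' @param gwp global warming potential (default 273).
#' @return flux in Tg CO2e yr^-1.
#' @export
#' @examples
#' n_to_co2e(583.0)   # 250.1
n_to_co2e <- function(flux_gg_n, gwp = 273) {
  if (any(flux_gg_n < 0)) stop("flux must be >= 0", call. = FALSE)
  flux_gg_n * (44 / 28) * gwp / 1000
}

#' Model-evaluation metrics
#'
#' `r2` is the squared Pearson correlation of the linear fit of simulated
#' on observed; `nse` is the Nash-Sutcliffe efficiency
#' `1 - sum((o - s)^2) / sum((o - mean(o))^2)` (1 perfect, 0 equals
#' predicting the observed mean).
#'
#' @param observed,simulated paired numeric series (>= 3 points).
#' @return list with `r2` and `nse`.
#' @export
validation_metrics <- function(observed, simulated) {
  if (length(observed) != length(simulated) || length(observed) < 3) {
    stop("need >= 3 paired points", call. = FALSE)
  }
  r2 <- if (stats::sd(simulated) == 0 || stats::sd(observed) == 0) {
    NA_real_                       # correlation undefined for a flat series
  } else stats::cor(observed, simulated)^2
  nse <- 1 - sum((observed - simulated)^2) / sum((observed - mean(observed))^2)
  list(r2 = r2, nse = nse)
}

#' IPCC-style leaching discount helper
#'
#' Converts a leaching-based emission factor (N2O-N emitted per unit N
#' *leached*) to the whole-addition basis used here, assuming a fixed
#' leached fraction of agricultural N additions (24% for managed soils in
#' wet climates).
#'
#' @param ef_leach_pct EF on the leached-N basis, percent.
#' @param leach_fraction fraction of additions leached (default 0.24).
#' @return EF on the additions basis, percent.
#' @export
discount_leaching_ef <- function(ef_leach_pct, leach_fraction = 0.24) {
  ef_leach_pct * leach_fraction
}

#' Country-level emission-factor table from scenario results
#'
#' Builds the per-decade, per-country EF record from the S1 and S6
#' scenario results: inland-water emissions are aggregated from the
#' element level to cells and countries; agricultural additions come from
#' the S1 world's per-cell addition series.
#'
#' @param s1,s6 `scenario_result`s (all-combined and agricultural-N-fixed).
#' @param network the `routing_network` both ran on.
#' @return data.frame: one `EFRecord` row per country x decade plus GLOBAL
#'   rows.
#' @export
ef_by_country <- function(s1, s6, network) {
  dec <- floor(s1$years / 10) * 10
  decades <- unique(dec)
  cc <- network$country
  out <- vector("list", length(decades))
  cell_sum <- function(emat, yrs) {
    e <- colMeans(emat[yrs, , drop = FALSE]) / 1e9      # Gg N/yr per element
    as.numeric(rowsum(e, network$cell_of))              # per cell
  }
  for (i in seq_along(decades)) {
    yrs <- base::which(dec == decades[i])
    e1 <- cell_sum(s1$emissions, yrs)
    e6 <- cell_sum(s6$emissions, yrs)
    add <- rowMeans(s1$ag_additions[, yrs, drop = FALSE]) / 1e9
    a1 <- aggregate_by_country(e1, cc)
    a6 <- aggregate_by_country(e6, cc)
    aa <- aggregate_by_country(add, cc)
    out[[i]] <- ef_ag(a1$value, a6$value, aa$value,
                      region = a1$region, decade = decades[i])
  }
  do.call(rbind, out)
}
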
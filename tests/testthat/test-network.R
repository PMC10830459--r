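# network module: graph building, classification, interception

test_that("cell_area_from_latitude matches the spherical-quadrangle oracle", {
  # independent evaluation of R^2 * dlambda * (sin phi2 - sin phi1)
  oracle <- function(lat, res) {
    R <- 6371000
    R^2 * (res * pi / 180) *
      (sin((lat + res / 2) * pi / 180) - sin((lat - res / 2) * pi / 180))
  }
  expect_equal(cell_area_from_latitude(0, 0.5), oracle(0, 0.5))
  expect_equal(cell_area_from_latitude(0, 0.5), 3.09e9, tolerance = 0.01)
  expect_equal(cell_area_from_latitude(45, 0.5), 2.19e9, tolerance = 0.01)
  # cosine shrinkage near the pole
  expect_lt(cell_area_from_latitude(89.75, 0.5) /
              cell_area_from_latitude(0, 0.5), 0.01)
  # pole-to-pole sum closes on the sphere area
  lats <- seq(-89.75, 89.75, by = 0.5)
  total <- sum(cell_area_from_latitude(lats, 0.5)) * 720
  expect_equal(total, 4 * pi * 6371000^2, tolerance = 1e-9)
  expect_error(cell_area_from_latitude(91, 0.5), "latitude")
  expect_error(cell_area_from_latitude(0, -1), "resolution")
})

test_that("classify_lentic follows the strict greater-than rule", {
  ca45 <- cell_area_from_latitude(45, 0.5)
  expect_equal(classify_lentic(3.0e9, ca45), "large")   # 3.0e9 > ~2.19e9
  expect_equal(classify_lentic(0, ca45), "small")
  expect_equal(classify_lentic(ca45, ca45), "small")    # tie breaks small
  expect_error(classify_lentic(-1, ca45), "non-negative")
  # monotone in upstream area
  ups <- sort(10^runif(50, 6, 11))
  cls <- classify_lentic(ups, 2e9)
  expect_false(is.unsorted(match(cls, c("small", "large"))))
})

test_that("build_network orders a chain and attaches bodies", {
  tabs <- chain_tables(lake_in_b = TRUE)
  net <- build_world(tabs)
  expect_s3_class(net, "routing_network")
  expect_equal(as.character(net$cells$cell_id[net$order]), c("A", "B"))
  expect_equal(net$n_elements, 5)        # 2 subnet + 2 main + 1 lake
  expect_equal(net$kind[net$e_body], "lake_small")
  # small body drains to its cell's main channel
  expect_equal(net$dest[net$e_body], net$e_main[2])
})

test_that("build_network rejects cycles and dangling references", {
  cells <- data.frame(cell_id = "X", lat = 45, lon = 0,
                      downstream_id = "X", country_code = 1)
  reaches <- rbind(
    data.frame(cell_id = "X", corridor = "subnetwork", length_m = 1e4,
               width_m = 5, slope = 1e-3),
    data.frame(cell_id = "X", corridor = "main", length_m = 1e4,
               width_m = 10, slope = 1e-3))
  expect_error(build_network(cells, reaches), "cycle.*X")

  tabs <- chain_tables(lake_in_b = FALSE)
  tabs$cells$downstream_id[1] <- "Z"
  expect_error(build_world(tabs), "dangling.*Z")

  # two-cell mutual cycle names both cells
  tabs <- chain_tables(lake_in_b = FALSE)
  tabs$cells$downstream_id <- c("B", "A")
  expect_error(build_world(tabs), "cycle")
})

test_that("generated 20x20 grid is fully drained (BFS oracle)", {
  tabs <- generate_network(n_side = 20, n_lakes = 8, n_reservoirs = 4, seed = 3)
  net <- build_world(tabs)
  # independent reachability check: hop down-links until the outlet
  idx <- stats::setNames(seq_len(400), as.character(tabs$cells$cell_id))
  reached <- rep(FALSE, 400)
  for (i in seq_len(400)) {
    cur <- i
    for (hop in 1:400) {
      d <- tabs$cells$downstream_id[cur]
      if (d == -1) { reached[i] <- TRUE; break }
      cur <- idx[[as.character(d)]]
    }
  }
  expect_true(all(reached))
  expect_equal(sum(tabs$cells$downstream_id == -1), 1)
  expect_equal(length(net$order), 400)
})

test_that("interception_fraction follows min(upstream/cell, 1)", {
  cell <- list(lat = 45)
  ca <- cell_area_from_latitude(45, 0.5)
  b <- list(upstream_m2 = 0.25 * ca, size_class = "small")
  expect_equal(interception_fraction(b, cell), 0.25)
  b$upstream_m2 <- 0
  expect_equal(interception_fraction(b, cell), 0)
  b$upstream_m2 <- 3 * ca
  expect_equal(interception_fraction(b, cell), 1)      # clamp
  b$size_class <- "large"
  expect_error(interception_fraction(b, cell), "small-class")
})

test_that("co-located small bodies intercept sequentially with total <= 1", {
  tabs <- chain_tables(lake_in_b = FALSE)
  ca <- cell_area_from_latitude(45.5, 0.5)
  tabs$bodies <- data.frame(
    body_id = c("L1", "L2", "L3"), cell_id = "A", kind = "lake",
    area_m2 = 1e6, volume_m3 = 5e6, depth_m = 5, residence_days = 50,
    upstream_m2 = c(0.6, 0.5, 0.9) * ca, built_year = NA_real_)
  net <- build_world(tabs)
  shares <- net$hs_share[net$e_body]
  # descending upstream area: L3 (0.9), L1 (0.6), L2 (0.5)
  expect_equal(shares[3], 0.9)
  expect_equal(shares[1], (1 - 0.9) * 0.6)
  expect_equal(shares[2], (1 - 0.9) * (1 - 0.6) * 0.5)
  expect_lte(sum(shares), 1)
  # residual feeds the subnetwork; the cell's split sums to one
  expect_equal(sum(shares) + net$hs_share[net$e_sub[1]], 1)
})

test_that("schema violations are caught by name", {
  tabs <- chain_tables()
  tabs$bodies$residence_days <- -1
  expect_error(build_world(tabs), "residence_days")
  tabs <- chain_tables()
  tabs$bodies$volume_m3 <- tabs$bodies$area_m2 * tabs$bodies$depth_m * 1.5
  expect_error(build_world(tabs), "volume")
  tabs <- chain_tables()
  tabs$bodies$built_year <- 1950            # lakes must not carry a year
  expect_error(build_world(tabs), "lakes")
})
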
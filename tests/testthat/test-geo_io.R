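test_that("loaded segment lengths match an independent vertex-sum oracle", {
  f <- tempfile(fileext = ".geojson")
  coords <- list(
    list(c(0, 0), c(300, 0)),
    list(c(0, 0), c(0, 100), c(100, 100)),
    list(c(500, 500), c(650, 650)))
  write_geojson_lines(f, lapply(seq_along(coords), function(i)
    list(type = "LineString", coordinates = coords[[i]],
         properties = list(segment_id = paste0("s", i)))))
  net <- load_network(f)
  expect_length(net$segments, 3)
  for (k in seq_along(coords)) {
    xy <- do.call(rbind, coords[[k]])
    oracle <- sum(sqrt(rowSums(diff(xy)^2)))
    expect_equal(net$segments[[k]]$length_m, oracle, tolerance = 1e-9)
  }
})

test_that("zero-length parts are dropped with a warning", {
  f <- tempfile(fileext = ".geojson")
  feats <- c(
    lapply(1:5, function(i)
      list(type = "LineString",
           coordinates = list(c(i * 10, 0), c(i * 10 + 5, 0)),
           properties = list(segment_id = paste0("s", i)))),
    list(list(type = "LineString",
              coordinates = list(c(0, 0), c(0, 0)),
              properties = list(segment_id = "zero"))))
  write_geojson_lines(f, feats[c(6, 1:5)])
  expect_warning(net <- load_network(f), "zero-length")
  expect_length(net$segments, 5)
})

test_that("MultiLineString features split into one segment per part", {
  f <- tempfile(fileext = ".geojson")
  write_geojson_lines(f, list(
    list(type = "MultiLineString",
         coordinates = list(list(c(0, 0), c(10, 0)),
                            list(c(20, 0), c(30, 0))),
         properties = list(segment_id = "m"))))
  net <- load_network(f)
  expect_setequal(vapply(net$segments, `[[`, "", "segment_id"),
                  c("m.1", "m.2"))
})

test_that("geographic input reprojects to UTM metres, against a geodesic oracle", {
  skip_if_not_installed("geosphere")
  f <- tempfile(fileext = ".geojson")
  # a ~1.6 km diagonal street in Kingston, Ontario (UTM zone 18N)
  lonlat <- list(c(-76.50, 44.23), c(-76.49, 44.24))
  write_geojson_lines(f, list(
    list(type = "LineString", coordinates = lonlat,
         properties = list(segment_id = "k"))), crs = "EPSG:4326")
  expect_error(load_network(f), "projected")
  net <- load_network(f, target_crs = "utm:18N")
  geo <- geosphere::distGeo(lonlat[[1]], lonlat[[2]])
  expect_gt(net$segments[[1]]$length_m, 0)
  expect_lt(abs(net$segments[[1]]$length_m - geo) / geo, 0.005)
})

test_that("missing CRS errors unless supplied", {
  f <- tempfile(fileext = ".geojson")
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature", properties = list(segment_id = "s"),
    geometry = list(type = "LineString",
                    coordinates = list(c(0, 0), c(10, 0))))))
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE), f)
  expect_error(load_network(f), "CRS")
  net <- load_network(f, source_crs = "local:meters")
  expect_length(net$segments, 1)
})

test_that("network round-trips through GeoJSON", {
  net <- make_tiny_network()
  f <- tempfile(fileext = ".geojson")
  write_network(net, f)
  back <- load_network(f)
  expect_identical(vapply(back$segments, `[[`, "", "segment_id"),
                   vapply(net$segments, `[[`, "", "segment_id"))
  for (k in seq_along(net$segments)) {
    expect_identical(nrow(back$segments[[k]]$polyline),
                     nrow(net$segments[[k]]$polyline))
    expect_equal(back$segments[[k]]$length_m, net$segments[[k]]$length_m,
                 tolerance = 1e-9)
  }
})

test_that("UTM projection round-trips and matches geodesic distances", {
  skip_if_not_installed("geosphere")
  set.seed(42)
  lon <- runif(20, -76.7, -76.3); lat <- runif(20, 44.1, 44.4)
  pr <- utm_forward(lon, lat, zone = 18, hemisphere = "N")
  ll <- utm_inverse(pr$xy[, 1], pr$xy[, 2], 18, "N")
  expect_equal(ll[, "lon"], lon, tolerance = 1e-9)
  expect_equal(ll[, "lat"], lat, tolerance = 1e-9)
  # projected distances agree with geodesic within UTM scale distortion
  for (i in 1:10) {
    d_proj <- sqrt(sum((pr$xy[2 * i, ] - pr$xy[2 * i - 1, ])^2))
    d_geo <- geosphere::distGeo(c(lon[2 * i - 1], lat[2 * i - 1]),
                                c(lon[2 * i], lat[2 * i]))
    expect_lt(abs(d_proj - d_geo) / d_geo, 0.005)
  }
})

test_that("most-recent-year resolution keeps the maximal year only", {
  tab <- data.frame(id = c("A", "A", "B"),
                    target_name = "vehicles",
                    value = c(10, 20, 5),
                    year = c(2017L, 2019L, 2018L))
  out <- resolve_most_recent(tab)
  expect_equal(nrow(out), 2)
  expect_equal(out$value[out$id == "A"], 20)
  # single-year table unchanged
  one <- data.frame(id = "A", target_name = "trees", value = 1, year = 2019L)
  expect_identical(resolve_most_recent(one), one)
  # equal maximal years are ambiguous
  amb <- data.frame(id = "A", target_name = "vehicles",
                    value = c(1, 2), year = c(2019L, 2019L))
  expect_error(resolve_most_recent(amb), "A")
})

test_that("ground-truth tables are validated on load", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = "z1", target_name = "trees", value = 3),
            f, row.names = FALSE)
  out <- load_ground_truth(f)
  expect_equal(out$value, 3)
  write.csv(data.frame(id = "z1", target_name = "nonsense", value = 3),
            f, row.names = FALSE)
  expect_error(load_ground_truth(f), "nonsense")
  write.csv(data.frame(id = "z1", target_name = "trees", value = -2),
            f, row.names = FALSE)
  expect_error(load_ground_truth(f), "non-negative")
})
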
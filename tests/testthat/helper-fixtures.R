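# Fixtures and independent brute-force oracles used across the suite.
# Oracles deliberately re-derive quantities by enumeration or naive
# algorithms, independent of the package's implementation path.

# small hand-built network: three straight segments in local metres
make_tiny_network <- function() {
  street_network(list(
    list(segment_id = "a", polyline = rbind(c(0, 0), c(100, 0)),
         road_class = "residential"),
    list(segment_id = "b", polyline = rbind(c(0, 0), c(0, 150)),
         road_class = "residential"),
    list(segment_id = "c", polyline = rbind(c(100, 0), c(100, 300), c(200, 300)),
         road_class = "arterial")
  ), crs_id = "local:meters")
}

write_geojson_lines <- function(path, features, crs = "local:meters") {
  feats <- lapply(features, function(f) {
    list(type = "Feature",
         properties = f$properties,
         geometry = list(type = f$type,
                         coordinates = f$coordinates))
  })
  gj <- list(type = "FeatureCollection",
             crs = list(type = "name", properties = list(name = crs)),
             features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA), path)
  path
}

# independent enumeration of the centred placement rule
oracle_offsets <- function(L, spacing) {
  n <- max(1, floor(L / spacing))
  vapply(seq_len(n), function(i) (i - 0.5) * L / n, 0)
}

# independent point-in-flat-top-hexagon test: a point is in the hexagon
# centred at c with circumradius R iff it is within R along all three hex
# axes (checked via the standard half-plane construction)
oracle_in_hex <- function(px, py, cx, cy, R) {
  dx <- abs(px - cx); dy <- abs(py - cy)
  w <- sqrt(3) / 2 * R
  dy <= w + 1e-9 && (sqrt(3) * dx + dy) <= sqrt(3) * R + 1e-9
}

# independent single-source shortest paths by Bellman-Ford on an edge list
oracle_shortest_paths <- function(edges, n_vertices, source) {
  d <- rep(Inf, n_vertices)
  d[source] <- 0
  for (iter in seq_len(n_vertices)) {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1]; v <- edges[e, 2]; w <- edges[e, 3]
      if (d[u] + w < d[v]) { d[v] <- d[u] + w; changed <- TRUE }
      if (d[v] + w < d[u]) { d[u] <- d[v] + w; changed <- TRUE }
    }
    if (!changed) break
  }
  d
}

# independent per-pixel counting loop
oracle_mask_fractions <- function(mask) {
  counts <- numeric(20)
  for (v in as.integer(mask)) {
    idx <- if (v == 255L) 20L else v + 1L
    counts[idx] <- counts[idx] + 1
  }
  counts / length(mask)
}

random_mask <- function(nr, nc, include_void = TRUE) {
  vals <- if (include_void) c(0:18, 255L) else 0:18
  matrix(sample(vals, nr * nc, replace = TRUE), nr, nc)
}

# summaries frame with known fractions for aggregation tests
make_summary_row <- function(point_id, heading, overrides = list()) {
  s <- as.list(stats::setNames(rep(0, 19), sv_classes()))
  s$void_fraction <- 0
  for (nm in names(overrides)) s[[nm]] <- overrides[[nm]]
  used <- sum(unlist(s[sv_classes()]))
  s$sky <- s$sky + max(0, 1 - used - s$void_fraction)
  cbind(data.frame(point_id = point_id, heading_deg = heading,
                   stringsAsFactors = FALSE),
        as.data.frame(s))
}
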
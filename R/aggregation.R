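# Zones (postal-code Manhattan buffers, intersection buffers), assignment of
# images to zones, and aggregation of class fractions into zone-level feature
# vectors.
#
# "Manhattan-style buffer" is implemented as the L1 (taxicab) ball by
# default; network-distance buffers (shortest-path distance along the street
# network, padded into a polygon) and Euclidean discs are available as
# alternatives. All regions are closed: points exactly on the boundary are
# inside.

#' Build a buffer zone around an anchor point
#'
#' @param anchor length-2 numeric (projected metres).
#' @param radius_m buffer radius in metres.
#' @param metric `"l1_diamond"` (default), `"euclidean_disc"` or `"network"`.
#' @param network a [street_network]; required for `metric = "network"`.
#' @param zone_id identifier for the zone.
#' @param kind `"postal_code"` or `"intersection"`.
#' @param buffer_pad_m for network zones, the pad (metres) turning covered
#'   street portions into an areal zone; default 25.
#' @return A `zone` object.
#' @export
build_zone <- function(anchor, radius_m,
                       metric = c("l1_diamond", "euclidean_disc", "network"),
                       network = NULL, zone_id = "zone", kind = "postal_code",
                       buffer_pad_m = 25) {
  metric <- match.arg(metric)
  anchor <- as.numeric(anchor)
  if (length(anchor) != 2 || !all(is.finite(anchor))) stopf("anchor must be a finite (x, y)")
  if (!is.numeric(radius_m) || radius_m <= 0) stopf("radius_m must be > 0")
  z <- list(zone_id = zone_id, kind = kind, anchor = anchor,
            radius_m = radius_m, metric = metric, buffer_pad_m = buffer_pad_m)
  if (metric == "l1_diamond") {
    z$polygon <- rbind(c(anchor[1] + radius_m, anchor[2]),
                       c(anchor[1], anchor[2] + radius_m),
                       c(anchor[1] - radius_m, anchor[2]),
                       c(anchor[1], anchor[2] - radius_m))
  } else if (metric == "euclidean_disc") {
    th <- seq(0, 2 * pi, length.out = 65)[-65]
    z$polygon <- cbind(anchor[1] + radius_m * cos(th),
                       anchor[2] + radius_m * sin(th))
  } else {
    if (!inherits(network, "street_network"))
      stopf("metric = 'network' requires a street_network")
    z$covered <- network_cover(network, anchor, radius_m)
    z$network_crs <- network$crs_id
  }
  structure(z, class = "zone")
}

#' @export
print.zone <- function(x, ...) {
  cat(sprintf("zone '%s' (%s): %s buffer, r = %g m, anchor (%.1f, %.1f)\n",
              x$zone_id, x$kind, x$metric, x$radius_m, x$anchor[1], x$anchor[2]))
  invisible(x)
}

# ---- network buffers --------------------------------------------------------

# Graph of segment endpoints; vertices keyed by rounded coordinates so
# segments sharing an endpoint connect.
network_graph <- function(network) {
  key <- function(p) sprintf("%.6f,%.6f", p[1], p[2])
  ends <- lapply(network$segments, function(s)
    list(u = key(s$polyline[1, ]), v = key(s$polyline[nrow(s$polyline), ]),
         w = s$length_m, id = s$segment_id))
  verts <- unique(unlist(lapply(ends, function(e) c(e$u, e$v))))
  el <- do.call(rbind, lapply(ends, function(e) c(e$u, e$v)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- vapply(ends, `[[`, 0, "w")
  igraph::E(g)$segment_id <- vapply(ends, `[[`, "", "id")
  list(graph = g, endpoint_keys = ends, key = key)
}

# Nearest location on the network to a point: segment id, arc offset,
# Euclidean gap. Works vertex-piece by vertex-piece.
nearest_on_network <- function(network, p) {
  best <- list(d = Inf)
  for (s in network$segments) {
    xy <- s$polyline
    cd <- polyline_cumdist(xy)
    for (i in seq_len(nrow(xy) - 1)) {
      a <- xy[i, ]; b <- xy[i + 1, ]
      ab <- b - a
      len2 <- sum(ab^2)
      t <- if (len2 > 0) max(0, min(1, sum((p - a) * ab) / len2)) else 0
      q <- a + t * ab
      d <- sqrt(sum((p - q)^2))
      if (d < best$d)
        best <- list(d = d, segment_id = s$segment_id,
                     offset = cd[i] + t * sqrt(len2), coord = q)
    }
  }
  best
}

# Covered arc-length intervals per segment within shortest-path radius of the
# network location nearest to `anchor`.
network_cover <- function(network, anchor, radius_m) {
  near <- nearest_on_network(network, anchor)
  if (near$d > radius_m)
    stopf("anchor is %.1f m from the network, farther than radius %.1f m",
          near$d, radius_m)
  ng <- network_graph(network)
  g <- ng$graph
  # Insert the source as a temporary vertex splitting the host segment.
  host <- network_segment(network, near$segment_id)
  uk <- ng$key(host$polyline[1, ])
  vk <- ng$key(host$polyline[nrow(host$polyline), ])
  g2 <- igraph::add_vertices(g, 1, name = "..src..")
  g2 <- igraph::add_edges(g2, c("..src..", uk, "..src..", vk),
                          weight = c(near$offset, host$length_m - near$offset))
  d <- igraph::distances(g2, v = "..src..")[1, ]
  cover <- list()
  for (s in network$segments) {
    L <- s$length_m
    du <- d[ng$key(s$polyline[1, ])]
    dv <- d[ng$key(s$polyline[nrow(s$polyline), ])]
    ivs <- list()
    if (s$segment_id == near$segment_id) {
      # distance within the host segment is measured from the anchor offset
      lo <- max(0, near$offset - radius_m)
      hi <- min(L, near$offset + radius_m)
      ivs[[1]] <- c(lo, hi)
    }
    if (is.finite(du) && du <= radius_m)
      ivs[[length(ivs) + 1]] <- c(0, min(L, radius_m - du))
    if (is.finite(dv) && dv <= radius_m)
      ivs[[length(ivs) + 1]] <- c(max(0, L - (radius_m - dv)), L)
    if (length(ivs)) {
      merged <- merge_intervals(ivs)
      if (length(merged)) cover[[s$segment_id]] <- merged
    }
  }
  cover
}

merge_intervals <- function(ivs) {
  ivs <- ivs[vapply(ivs, function(v) v[2] > v[1], TRUE)]
  if (!length(ivs)) return(list())
  m <- do.call(rbind, ivs)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- list(m[1, ])
  for (i in seq_len(nrow(m))[-1]) {
    last <- out[[length(out)]]
    if (m[i, 1] <= last[2]) out[[length(out)]] <- c(last[1], max(last[2], m[i, 2]))
    else out[[length(out) + 1]] <- m[i, ]
  }
  out
}

# Sub-polyline of a segment between arc offsets [s0, s1].
sub_polyline <- function(xy, s0, s1) {
  cd <- polyline_cumdist(xy)
  p0 <- polyline_interpolate(xy, s0)
  p1 <- polyline_interpolate(xy, s1)
  mid <- which(cd > s0 & cd < s1)
  rbind(p0, xy[mid, , drop = FALSE], p1)
}

point_to_polyline_dist <- function(p, xy) {
  best <- Inf
  for (i in seq_len(nrow(xy) - 1)) {
    a <- xy[i, ]; b <- xy[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 > 0) max(0, min(1, sum((p - a) * ab) / len2)) else 0
    q <- a + t * ab
    best <- min(best, sqrt(sum((p - q)^2)))
  }
  best
}

# ---- membership -------------------------------------------------------------

#' Test zone membership for points
#'
#' Closed-region decision: boundary points are inside. For `l1_diamond` the
#' predicate is |dx| + |dy| <= r; for `euclidean_disc` it is the Euclidean
#' distance; for `network` a point is inside when it lies within the pad
#' distance of a street portion reachable within the radius.
#'
#' @param zone a [build_zone] result.
#' @param x,y coordinate vectors (projected metres).
#' @return Logical vector.
#' @export
zone_contains <- function(zone, x, y) {
  if (zone$metric == "l1_diamond")
    return(abs(x - zone$anchor[1]) + abs(y - zone$anchor[2]) <= zone$radius_m)
  if (zone$metric == "euclidean_disc")
    return((x - zone$anchor[1])^2 + (y - zone$anchor[2])^2 <= zone$radius_m^2)
  pieces <- zone_cover_polylines(zone)
  vapply(seq_along(x), function(i) {
    p <- c(x[i], y[i])
    for (xy in pieces)
      if (point_to_polyline_dist(p, xy) <= zone$buffer_pad_m) return(TRUE)
    FALSE
  }, TRUE)
}

# Covered sub-polylines of a network zone (needs the generating network's
# segment geometry, cached on first use via the zone's stored cover and the
# network passed to build_zone).
zone_cover_polylines <- function(zone) {
  if (!is.null(zone$cover_polylines)) return(zone$cover_polylines)
  stopf("network zone is missing its cover geometry")
}

#' Attach covered street geometry to a network zone
#'
#' Needed once, after [build_zone] with `metric = "network"`, so membership
#' tests and GeoJSON export can use the covered sub-polylines.
#' @param zone a network-metric zone.
#' @param network the [street_network] the zone was built on.
#' @return The zone with geometry attached.
#' @export
zone_attach_geometry <- function(zone, network) {
  if (zone$metric != "network") return(zone)
  pieces <- list()
  for (sid in names(zone$covered)) {
    s <- network_segment(network, sid)
    for (iv in zone$covered[[sid]])
      pieces[[length(pieces) + 1]] <- sub_polyline(s$polyline, iv[1], iv[2])
  }
  zone$cover_polylines <- pieces
  zone
}

# ---- clipping ---------------------------------------------------------------

# Length of the part of linear piece A->B lying inside the zone.
clip_piece_length <- function(zone, a, b) {
  len <- sqrt(sum((b - a)^2))
  if (len == 0) return(0)
  if (zone$metric == "l1_diamond") {
    # f(t) = |ax + t dx| + |ay + t dy| is piecewise linear; breakpoints where
    # either coordinate offset crosses zero.
    ax <- a[1] - zone$anchor[1]; ay <- a[2] - zone$anchor[2]
    dx <- b[1] - a[1]; dy <- b[2] - a[2]
    ts <- c(0, 1)
    if (dx != 0) { t0 <- -ax / dx; if (t0 > 0 && t0 < 1) ts <- c(ts, t0) }
    if (dy != 0) { t0 <- -ay / dy; if (t0 > 0 && t0 < 1) ts <- c(ts, t0) }
    ts <- sort(unique(ts))
    f <- function(t) abs(ax + t * dx) + abs(ay + t * dy)
    inside <- 0
    for (i in seq_len(length(ts) - 1)) {
      t1 <- ts[i]; t2 <- ts[i + 1]
      f1 <- f(t1); f2 <- f(t2); r <- zone$radius_m
      if (f1 <= r && f2 <= r) inside <- inside + (t2 - t1)
      else if (f1 <= r || f2 <= r) {
        tc <- t1 + (r - f1) / (f2 - f1) * (t2 - t1)
        inside <- inside + if (f1 <= r) (tc - t1) else (t2 - tc)
      }
    }
    return(inside * len)
  }
  if (zone$metric == "euclidean_disc") {
    # |a + t d - c|^2 = r^2 is quadratic in t
    ac <- a - zone$anchor
    d <- b - a
    A <- sum(d^2); B <- 2 * sum(ac * d); C <- sum(ac^2) - zone$radius_m^2
    disc <- B^2 - 4 * A * C
    if (disc <= 0) return(if (C <= 0) len else 0)
    r1 <- (-B - sqrt(disc)) / (2 * A); r2 <- (-B + sqrt(disc)) / (2 * A)
    lo <- max(0, min(r1, r2)); hi <- min(1, max(r1, r2))
    return(max(0, hi - lo) * len)
  }
  stopf("clip_piece_length does not apply to metric '%s'", zone$metric)
}

# Length of the portion of a whole segment polyline inside the zone.
clip_segment_length <- function(zone, segment) {
  if (zone$metric == "network") {
    ivs <- zone$covered[[segment$segment_id]]
    if (is.null(ivs)) return(0)
    return(sum(vapply(ivs, function(v) v[2] - v[1], 0)))
  }
  xy <- segment$polyline
  sum(vapply(seq_len(nrow(xy) - 1), function(i)
    clip_piece_length(zone, xy[i, ], xy[i + 1, ]), 0))
}

# ---- aggregation ------------------------------------------------------------

#' Points whose images contribute to a zone
#'
#' Non-excluded sample points whose coordinate lies inside or on the zone.
#' @param points data.frame of sample points.
#' @param zone a zone.
#' @return Subset of `points`.
#' @export
assign_images <- function(points, zone) {
  keep <- !points$excluded & zone_contains(zone, points$x, points$y)
  points[keep, , drop = FALSE]
}

#' Aggregate image summaries into a zone feature vector
#'
#' Unweighted mean over contributing images (not points), so points with
#' partial imagery contribute proportionally. Duplicate (point_id, heading)
#' rows are de-duplicated first.
#'
#' @param summaries data.frame with `point_id`, `heading_deg` and class
#'   fraction columns.
#' @param zone a zone.
#' @param points data.frame of sample points.
#' @return One-row data.frame (`zone_id`, `n_points`, `n_images`, class
#'   means), or `NULL` with a warning when no image contributes.
#' @export
aggregate_zone <- function(summaries, zone, points) {
  inside <- assign_images(points, zone)
  contrib <- summaries[summaries$point_id %in% inside$point_id, , drop = FALSE]
  contrib <- contrib[!duplicated(contrib[c("point_id", "heading_deg")]), , drop = FALSE]
  if (nrow(contrib) == 0) {
    warnf("zone '%s' has no contributing images; flagged missing", zone$zone_id)
    return(NULL)
  }
  cls <- intersect(c(sv_classes(), "void_fraction", sv_collapsed_classes()),
                   names(contrib))
  means <- colMeans(contrib[cls])
  out <- data.frame(zone_id = zone$zone_id,
                    n_points = length(unique(contrib$point_id)),
                    n_images = nrow(contrib), stringsAsFactors = FALSE)
  out[names(means)] <- as.list(means)
  out
}

#' Aggregate many zones into a feature table
#' @param summaries image summaries data.frame.
#' @param zones list of zones.
#' @param points sample points data.frame.
#' @return data.frame, one row per non-empty zone.
#' @export
aggregate_zones <- function(summaries, zones, points) {
  rows <- lapply(zones, function(z) aggregate_zone(summaries, z, points))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-segment sidewalk label from image summaries
#'
#' A segment is labelled sidewalk-positive when any contributing image on it
#' shows a sidewalk fraction of at least `tau`. The presence threshold `tau`
#' (default 0.005 of image area) makes the binary "detected" decision
#' explicit for fraction-valued summaries.
#'
#' @param points sample points data.frame (maps point to segment).
#' @param summaries image summaries data.frame with a `sidewalk` column.
#' @param tau detection threshold on the sidewalk fraction.
#' @return data.frame `segment_id`, `sidewalk_pred` (logical; `NA` for
#'   segments with no imagery).
#' @export
sidewalk_segment_labels <- function(points, summaries, tau = 0.005) {
  pts <- points[!points$excluded, , drop = FALSE]
  seg_of <- pts$segment_id[match(summaries$point_id, pts$point_id)]
  ok <- !is.na(seg_of)
  det <- tapply(summaries$sidewalk[ok] >= tau, seg_of[ok], any)
  segs <- unique(points$segment_id)
  data.frame(segment_id = segs,
             sidewalk_pred = as.logical(det[segs]),
             stringsAsFactors = FALSE)
}

#' Metres of sidewalk-positive road inside a zone
#'
#' Sums the lengths of positively labelled segments clipped to the zone.
#'
#' @param network a [street_network].
#' @param labels data.frame `segment_id`, `sidewalk_pred`.
#' @param zone a zone.
#' @return Metres (numeric scalar).
#' @export
sidewalk_length_per_zone <- function(network, labels, zone) {
  pos <- labels$segment_id[!is.na(labels$sidewalk_pred) & labels$sidewalk_pred]
  total <- 0
  for (s in network$segments)
    if (s$segment_id %in% pos)
      total <- total + clip_segment_length(zone, s)
  total
}

#' Write zones to GeoJSON polygons
#' @param zones list of zones (network zones need [zone_attach_geometry]).
#' @param path output file.
#' @param crs_id CRS recorded in the file.
#' @export
write_zones <- function(zones, path, crs_id = "local:meters") {
  ring <- function(m) {
    m <- rbind(m, m[1, , drop = FALSE])
    lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  }
  feats <- lapply(zones, function(z) {
    geom <- if (z$metric == "network") {
      polys <- lapply(zone_cover_polylines(z), function(xy) {
        # pad each covered piece into a rectangle-ish hull
        d <- xy[nrow(xy), ] - xy[1, ]
        n <- if (sum(d^2) > 0) c(-d[2], d[1]) / sqrt(sum(d^2)) else c(0, 1)
        pad <- z$buffer_pad_m
        list(ring(rbind(xy[1, ] + n * pad, xy[nrow(xy), ] + n * pad,
                        xy[nrow(xy), ] - n * pad, xy[1, ] - n * pad)))
      })
      list(type = "MultiPolygon", coordinates = polys)
    } else {
      list(type = "Polygon", coordinates = list(ring(z$polygon)))
    }
    list(type = "Feature",
         properties = list(zone_id = z$zone_id, kind = z$kind,
                           radius_m = z$radius_m, metric = z$metric),
         geometry = geom)
  })
  gj <- list(type = "FeatureCollection",
             crs = list(type = "name", properties = list(name = crs_id)),
             features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
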
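# Choosing image-sampling points along the network, building the four
# cardinal-direction image requests per point, and thinning point sets with a
# hexagonal grid.
#
# Placement rule: with segment length L and spacing s, n = max(1, floor(L/s))
# points are placed at offsets (i - 0.5) * L / n. The centred rule is chosen
# because a segment shorter than the spacing then receives exactly one point
# at its midpoint, and points are evenly spread with half-interval margins at
# the segment ends.

#' Sample points at fixed intervals along a street network
#'
#' @param network a [street_network].
#' @param spacing_m sampling interval in metres (default 150).
#' @return data.frame with columns `point_id`, `segment_id`, `offset_m`,
#'   `x`, `y`, `excluded` (all `FALSE` until imagery availability is known).
#' @export
sample_points <- function(network, spacing_m = 150) {
  stopifnot(inherits(network, "street_network"))
  if (!is.numeric(spacing_m) || spacing_m <= 0) stopf("spacing_m must be > 0")
  if (length(network$segments) == 0) {
    warnf("empty network: no points sampled")
    return(data.frame(point_id = character(), segment_id = character(),
                      offset_m = numeric(), x = numeric(), y = numeric(),
                      excluded = logical()))
  }
  rows <- lapply(network$segments, function(s) {
    L <- s$length_m
    n <- max(1L, floor(L / spacing_m))
    off <- (seq_len(n) - 0.5) * L / n
    xy <- t(vapply(off, function(o) polyline_interpolate(s$polyline, o),
                   numeric(2)))
    data.frame(point_id = sprintf("%s:p%03d", s$segment_id, seq_len(n)),
               segment_id = s$segment_id, offset_m = off,
               x = xy[, 1], y = xy[, 2], excluded = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$segment_id, out$offset_m), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build cardinal-direction image requests for sample points
#'
#' Each non-excluded point yields four requests with headings 0, 90, 180 and
#' 270 degrees; latitude/longitude are obtained by inverse projection from
#' the network CRS.
#'
#' @param points data.frame from [sample_points].
#' @param crs_id the projected CRS the point coordinates are in.
#' @return data.frame with columns `point_id`, `heading_deg`, `lat`, `lon`,
#'   `status` (initially `"pending"`).
#' @export
make_requests <- function(points, crs_id) {
  pts <- points[!points$excluded, , drop = FALSE]
  if (nrow(pts) == 0)
    return(data.frame(point_id = character(), heading_deg = integer(),
                      lat = numeric(), lon = numeric(), status = character()))
  ll <- crs_to_lonlat(pts$x, pts$y, crs_id)
  headings <- c(0L, 90L, 180L, 270L)
  out <- data.frame(
    point_id = rep(pts$point_id, each = 4L),
    heading_deg = rep(headings, times = nrow(pts)),
    lat = rep(ll[, "lat"], each = 4L),
    lon = rep(ll[, "lon"], each = 4L),
    status = "pending",
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Mark points with no available imagery as excluded
#'
#' A point whose four requests all came back missing is excluded from the
#' analysis. Points with partial imagery (1-3 of 4 images) stay included;
#' only their fetched images contribute downstream.
#'
#' @param points data.frame from [sample_points].
#' @param fetch_results data.frame with `point_id`, `heading_deg`, `status`
#'   in `fetched`/`missing`.
#' @return `points` with `excluded` updated.
#' @export
mark_missing <- function(points, fetch_results) {
  fetched <- tapply(fetch_results$status == "fetched", fetch_results$point_id, sum)
  n_fetched <- fetched[points$point_id]
  n_fetched[is.na(n_fetched)] <- 0
  points$excluded <- n_fetched == 0
  points
}

# Flat-top hexagon geometry. `cell_width_m` is the width across the flat
# sides (the cell diameter as usually quoted for hex grids); the circumradius
# is width / sqrt(3).
hex_axial <- function(x, y, size) {
  q <- (2 / 3) * x / size
  r <- (-1 / 3 * x + sqrt(3) / 3 * y) / size
  # cube rounding
  s <- -q - r
  rq <- round(q); rr <- round(r); rs <- round(s)
  dq <- abs(rq - q); dr <- abs(rr - r); ds <- abs(rs - s)
  fix_q <- dq > dr & dq > ds
  fix_r <- !fix_q & dr > ds
  rq[fix_q] <- -rr[fix_q] - rs[fix_q]
  rr[fix_r] <- -rq[fix_r] - rs[fix_r]
  cbind(q = rq, r = rr)
}

hex_center <- function(q, r, size) {
  cbind(x = size * 3 / 2 * q, y = size * sqrt(3) * (r + q / 2))
}

#' Thin sample points with a hexagonal grid
#'
#' Covers the points' bounding box with a flat-top hexagonal grid and keeps,
#' per occupied cell, the single point nearest the cell centroid (ties broken
#' by lexicographically smallest `point_id`).
#'
#' @param points data.frame of points with `point_id`, `x`, `y`.
#' @param cell_width_m hexagon width across the flat sides, metres.
#' @return The retained subset of `points`, in the original order.
#' @export
hex_downsample <- function(points, cell_width_m) {
  if (nrow(points) == 0) stopf("hex_downsample requires a non-empty point set")
  if (!is.numeric(cell_width_m) || cell_width_m <= 0)
    stopf("cell_width_m must be > 0")
  size <- cell_width_m / sqrt(3)  # circumradius of flat-top hexagon
  ax <- hex_axial(points$x, points$y, size)
  key <- paste(ax[, "q"], ax[, "r"], sep = ",")
  ctr <- hex_center(ax[, "q"], ax[, "r"], size)
  d2 <- (points$x - ctr[, "x"])^2 + (points$y - ctr[, "y"])^2
  keep <- unlist(lapply(split(seq_len(nrow(points)), key), function(idx) {
    best <- idx[d2[idx] == min(d2[idx])]
    if (length(best) > 1) best <- best[order(points$point_id[best])][1]
    best
  }), use.names = FALSE)
  out <- points[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write sample points to GeoJSON
#' @param points data.frame of points.
#' @param path output file.
#' @param crs_id CRS identifier recorded in the file.
#' @export
write_points <- function(points, path, crs_id = "local:meters") {
  feats <- lapply(seq_len(nrow(points)), function(i) {
    list(type = "Feature",
         properties = list(point_id = points$point_id[i],
                           segment_id = points$segment_id[i],
                           offset_m = points$offset_m[i],
                           excluded = points$excluded[i]),
         geometry = list(type = "Point",
                         coordinates = c(points$x[i], points$y[i])))
  })
  gj <- list(type = "FeatureCollection",
             crs = list(type = "name", properties = list(name = crs_id)),
             features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
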
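# Reading and writing street networks, zones and ground-truth tables, and the
# coordinate conventions enforced on ingestion. All internal geometry is in a
# projected CRS in metres; geographic (degree) inputs are reprojected at load
# because every distance in the method (150 m sampling interval, 500 m
# buffers, the 50-2000 m sweep) is metric.

#' Construct a street network
#'
#' @param segments list of road segments; each a list with `segment_id`,
#'   `polyline` (n x 2 matrix, metres), and optionally `sidewalk_truth`
#'   (logical) and `road_class` (character).
#' @param crs_id coordinate reference identifier (projected, metres).
#' @return A `street_network` object.
#' @export
street_network <- function(segments, crs_id = "local:meters") {
  crs <- parse_crs(crs_id)
  if (!is.null(crs) && crs$kind == "geographic")
    stopf("street_network requires a projected CRS in metres, not '%s'", crs_id)
  segments <- lapply(segments, function(s) {
    xy <- as.matrix(s$polyline)
    storage.mode(xy) <- "double"
    colnames(xy) <- c("x", "y")
    if (nrow(xy) < 2) stopf("segment '%s' has fewer than 2 vertices", s$segment_id)
    if (!all(is.finite(xy))) stopf("segment '%s' has non-finite coordinates", s$segment_id)
    s$polyline <- xy
    s$length_m <- polyline_length(xy)
    if (s$length_m <= 0) stopf("segment '%s' has zero length", s$segment_id)
    s$sidewalk_truth <- if (is.null(s$sidewalk_truth)) NA else as.logical(s$sidewalk_truth)
    s$road_class <- if (is.null(s$road_class)) NA_character_ else as.character(s$road_class)
    s[c("segment_id", "polyline", "length_m", "sidewalk_truth", "road_class")]
  })
  ids <- vapply(segments, `[[`, "", "segment_id")
  if (anyDuplicated(ids)) stopf("duplicate segment ids: %s",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(segments = segments, crs_id = crs_id, units = "meters"),
            class = "street_network")
}

#' @export
print.street_network <- function(x, ...) {
  cat(sprintf("street_network: %d segments, %.1f km total, CRS %s\n",
              length(x$segments),
              sum(vapply(x$segments, `[[`, 0, "length_m")) / 1000,
              x$crs_id))
  invisible(x)
}

#' @export
summary.street_network <- function(object, ...) {
  len <- vapply(object$segments, `[[`, 0, "length_m")
  cls <- vapply(object$segments, `[[`, "", "road_class")
  cat(sprintf("street_network with %d segments (CRS %s)\n", length(len), object$crs_id))
  cat(sprintf("  total length: %.1f km; segment length range: %.1f-%.1f m\n",
              sum(len) / 1000, min(len), max(len)))
  if (!all(is.na(cls))) print(table(road_class = cls, useNA = "ifany"))
  invisible(object)
}

network_segment <- function(network, segment_id) {
  ids <- vapply(network$segments, `[[`, "", "segment_id")
  i <- match(segment_id, ids)
  if (is.na(i)) stopf("no segment '%s' in network", segment_id)
  network$segments[[i]]
}

geojson_crs_id <- function(gj) {
  crs <- gj$crs
  if (is.null(crs)) return(NULL)
  nm <- crs$properties$name
  if (is.null(nm)) NULL else as.character(nm)
}

coords_to_matrix <- function(coords) {
  do.call(rbind, lapply(coords, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
}

#' Load a street network from GeoJSON
#'
#' Reads LineString / MultiLineString features. MultiLineStrings are split
#' into one segment per part (suffix `.1`, `.2`, ...) since the per-segment
#' sidewalk classification unit is the individual polyline. Zero-length parts
#' are dropped with a warning. Geographic (degree) input is reprojected to
#' UTM metres; the file must declare a CRS (a `crs` member) or one must be
#' supplied via `source_crs`.
#'
#' @param path GeoJSON file.
#' @param target_crs projected CRS to reproject into (e.g. `"utm:18N"` or
#'   `"EPSG:32618"`). Required when the source is geographic.
#' @param source_crs CRS of the file if the file does not declare one.
#' @return A [street_network].
#' @export
load_network <- function(path, target_crs = NULL, source_crs = NULL) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stopf("'%s' is not a GeoJSON FeatureCollection", path)
  crs_id <- geojson_crs_id(gj)
  if (is.null(crs_id)) crs_id <- source_crs
  if (is.null(crs_id))
    stopf("network file declares no CRS and none was supplied via source_crs")
  src <- parse_crs(crs_id)

  segs <- list()
  dropped <- 0L
  for (k in seq_along(gj$features)) {
    f <- gj$features[[k]]
    geom <- f$geometry
    props <- f$properties
    sid <- props$segment_id
    if (is.null(sid)) sid <- props$id
    if (is.null(sid)) sid <- sprintf("seg%04d", k)
    parts <- switch(geom$type,
      LineString = list(geom$coordinates),
      MultiLineString = geom$coordinates,
      next)
    for (j in seq_along(parts)) {
      xy <- coords_to_matrix(parts[[j]])
      pid <- if (length(parts) > 1) sprintf("%s.%d", sid, j) else as.character(sid)
      if (nrow(xy) < 2 || polyline_length(xy) <= 0) {
        dropped <- dropped + 1L
        next
      }
      segs[[length(segs) + 1L]] <- list(
        segment_id = pid, polyline = xy,
        sidewalk_truth = props$sidewalk_truth,
        road_class = props$road_class)
    }
  }
  if (dropped > 0)
    warnf("dropped %d zero-length segment part(s) from '%s'", dropped, path)

  if (src$kind == "geographic") {
    tgt <- parse_crs(target_crs)
    if (is.null(tgt) || tgt$kind != "utm")
      stopf(paste0("network '%s' is in geographic degrees; supply a projected ",
                   "target_crs such as 'utm:18N' or 'EPSG:32618'"), path)
    segs <- lapply(segs, function(s) {
      pr <- utm_forward(s$polyline[, 1], s$polyline[, 2],
                        zone = tgt$zone, hemisphere = tgt$hemisphere)
      s$polyline <- pr$xy
      s
    })
    crs_id <- tgt$id
  }
  street_network(segs, crs_id = crs_id)
}

#' Write a street network to GeoJSON
#'
#' @param network a [street_network].
#' @param path output file.
#' @export
write_network <- function(network, path) {
  feats <- lapply(network$segments, function(s) {
    list(type = "Feature",
         properties = list(segment_id = s$segment_id,
                           sidewalk_truth = if (is.na(s$sidewalk_truth)) NULL else s$sidewalk_truth,
                           road_class = if (is.na(s$road_class)) NULL else s$road_class,
                           length_m = s$length_m),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(s$polyline)),
                                              function(i) as.numeric(s$polyline[i, ]))))
  })
  gj <- list(type = "FeatureCollection",
             crs = list(type = "name", properties = list(name = network$crs_id)),
             features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA, null = "null"), path)
  invisible(path)
}

#' Load a ground-truth table
#'
#' CSV with header `id,target_name,value[,year]`. Values are kept in their
#' native units; standardization happens at modelling time because different
#' cities may define the same target differently (e.g. annualized versus
#' rush-hour traffic counts).
#'
#' @param path CSV file.
#' @return data.frame with columns `id`, `target_name`, `value`, `year`.
#' @export
load_ground_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "target_name", "value")
  if (!all(need %in% names(df)))
    stopf("ground-truth table must have columns %s", paste(need, collapse = ", "))
  if (!"year" %in% names(df)) df$year <- NA_integer_
  bad <- setdiff(unique(df$target_name), sv_target_names())
  if (length(bad))
    stopf("unknown target_name(s): %s", paste(bad, collapse = ", "))
  if (any(!is.finite(df$value)) || any(df$value < 0))
    stopf("ground-truth values must be finite and non-negative")
  df[c("id", "target_name", "value", "year")]
}

#' The seven ground-truth target names
#' @export
sv_target_names <- function() {
  c("trees", "sidewalk_length", "pedestrians", "bicycles", "vehicles",
    "traffic_lights", "traffic_signs")
}

#' Keep only the most recent year per (id, target)
#'
#' Where a ground-truth table carries multiple years for the same id and
#' target, the most recent year's row is retained.
#'
#' @param table data.frame as from [load_ground_truth].
#' @return data.frame with exactly one row per (id, target_name).
#' @export
resolve_most_recent <- function(table) {
  key <- interaction(table$id, table$target_name, drop = TRUE)
  keep <- unlist(lapply(split(seq_len(nrow(table)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    yrs <- table$year[idx]
    if (any(is.na(yrs)))
      stopf("duplicate rows without year for id '%s'", table$id[idx[1]])
    best <- idx[yrs == max(yrs)]
    if (length(best) > 1)
      stopf("ambiguous duplicate rows (equal maximal year %d) for id '%s'",
            max(yrs), table$id[idx[1]])
    best
  }), use.names = FALSE)
  out <- table[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
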
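# End-to-end orchestration of the five pipeline stages -- sample points,
# obtain imagery, segment/summarize, aggregate to zones, model -- with a run
# manifest (config snapshot, seeds, stage timestamps, output digests) for
# reproducibility. Stages are resumable: an output already on disk with a
# recorded digest is reused rather than recomputed.

#' Default pipeline configuration
#'
#' @param seed master seed; all stage sub-seeds derive from it.
#' @param city named list of [city_config] arguments for the synthetic city.
#' @param spacing_m sampling interval (150 m).
#' @param n_zones number of postal-code-like zone centroids.
#' @param zone_radius_m zone buffer radius (500 m).
#' @param zone_metric `"l1_diamond"` (Manhattan-style), `"euclidean_disc"`
#'   or `"network"`.
#' @param intersection_buffers named buffer radii for the intersection
#'   traffic targets.
#' @param families model families to fit.
#' @param tau sidewalk detection threshold.
#' @return A config list.
#' @export
pipeline_config <- function(seed = 1L, city = list(), spacing_m = 150,
                            n_zones = 60, zone_radius_m = 500,
                            zone_metric = "l1_diamond",
                            intersection_buffers = c(pedestrians = 1000,
                                                     bicycles = 1000,
                                                     vehicles = 500),
                            families = c("linear", "gbt", "svm"),
                            tau = 0.005) {
  list(seed = as.integer(seed), city = city, spacing_m = spacing_m,
       n_zones = n_zones, zone_radius_m = zone_radius_m,
       zone_metric = zone_metric,
       intersection_buffers = intersection_buffers,
       families = families, tau = tau)
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  do.call(pipeline_config, config[intersect(names(config),
                                            names(formals(pipeline_config)))])
}

write_csv_stable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full pipeline on a synthetic city
#'
#' Stages: `synth` (network + ground truth), `sample` (points), `summarize`
#' (image summaries), `aggregate` (zone feature vectors + zone truth),
#' `model` (cross-validated fits for the seven targets). A stage whose
#' outputs already exist is reused when `resume = TRUE`; requesting a late
#' stage without its inputs on disk is an error naming the gap.
#'
#' @param config a config list from [pipeline_config], or a YAML file path.
#' @param out_dir output directory.
#' @param stages subset of stages to run (in pipeline order).
#' @param resume reuse stage outputs already on disk.
#' @return The run manifest (invisibly); outputs are written under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("synth", "sample", "summarize",
                                    "aggregate", "model"),
                         resume = TRUE) {
  cfg <- read_pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)
  manifest <- list(config = cfg, seed = cfg$seed, stages = list())
  mark <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      outputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files))))
    manifest
  }
  need <- function(stage, file, producer) {
    if (!file.exists(file))
      stopf("stage '%s' requires '%s' produced by stage '%s'; run it first",
            stage, basename(file), producer)
  }

  ccfg <- do.call(city_config, c(list(seed = cfg$seed), cfg$city))
  network <- NULL; truth <- NULL; points <- NULL; summaries <- NULL

  if ("synth" %in% stages) {
    if (!(resume && all(file.exists(pth(c("net.geojson", "trees.csv",
                                          "sidewalks.csv", "intersections.csv")))))) {
      network <- gen_network(ccfg)
      truth <- gen_ground_truth(network, ccfg)
      write_network(network, pth("net.geojson"))
      write_csv_stable(truth$trees, pth("trees.csv"))
      write_csv_stable(truth$sidewalks, pth("sidewalks.csv"))
      write_csv_stable(truth$intersections, pth("intersections.csv"))
    }
    manifest <- mark("synth", pth(c("net.geojson", "trees.csv",
                                    "sidewalks.csv", "intersections.csv")))
  }
  load_synth <- function() {
    if (is.null(network)) {
      network <<- gen_network(ccfg)
      truth <<- gen_ground_truth(network, ccfg)
    }
  }

  if ("sample" %in% stages) {
    need("sample", pth("net.geojson"), "synth")
    if (resume && all(file.exists(pth(c("points.csv", "points.geojson"))))) {
      points <- utils::read.csv(pth("points.csv"))
    } else {
      load_synth()
      points <- sample_points(network, cfg$spacing_m)
      write_csv_stable(points, pth("points.csv"))
      write_points(points, pth("points.geojson"), network$crs_id)
    }
    manifest <- mark("sample", pth(c("points.csv", "points.geojson")))
  }

  if ("summarize" %in% stages) {
    need("summarize", pth("points.csv"), "sample")
    if (resume && file.exists(pth("summaries.csv"))) {
      summaries <- utils::read.csv(pth("summaries.csv"))
    } else {
      load_synth()
      if (is.null(points)) points <- utils::read.csv(pth("points.csv"))
      summaries <- render_summaries(points, truth, ccfg)
      write_csv_stable(summaries, pth("summaries.csv"))
    }
    manifest <- mark("summarize", pth("summaries.csv"))
  }

  zones_of <- function(centroids) lapply(seq_len(nrow(centroids)), function(i)
    build_zone(c(centroids$x[i], centroids$y[i]), cfg$zone_radius_m,
               cfg$zone_metric, network = network,
               zone_id = centroids$zone_id[i]))

  if ("aggregate" %in% stages || "model" %in% stages) {
    need("aggregate", pth("summaries.csv"), "summarize")
    load_synth()
    if (is.null(points)) points <- utils::read.csv(pth("points.csv"))
    if (is.null(summaries)) summaries <- utils::read.csv(pth("summaries.csv"))
    centroids <- gen_zone_centroids(ccfg, cfg$n_zones)
    zones <- zones_of(centroids)
    feats <- aggregate_zones(summaries, zones, points)
    labels <- sidewalk_segment_labels(points, summaries, cfg$tau)
    truth_lab <- data.frame(segment_id = truth$sidewalks$segment_id,
                            sidewalk_pred = truth$sidewalks$sidewalk_truth)
    zone_truth <- data.frame(
      zone_id = centroids$zone_id,
      trees = vapply(zones, function(z) zone_tree_count(truth$trees, z), 0),
      sidewalk_length = vapply(zones, function(z)
        sidewalk_length_per_zone(network, truth_lab, z), 0),
      traffic_lights = vapply(zones, function(z)
        sum(truth$intersections$n_lights[
          zone_contains(z, truth$intersections$x, truth$intersections$y)]), 0),
      traffic_signs = vapply(zones, function(z)
        sum(truth$intersections$n_signs[
          zone_contains(z, truth$intersections$x, truth$intersections$y)]), 0))
    write_csv_stable(feats, pth("zone_features.csv"))
    write_csv_stable(zone_truth, pth("zone_truth.csv"))
    write_csv_stable(labels, pth("sidewalk_labels.csv"))
    manifest <- mark("aggregate", pth(c("zone_features.csv", "zone_truth.csv",
                                        "sidewalk_labels.csv")))
  }

  if ("model" %in% stages) {
    feats <- utils::read.csv(pth("zone_features.csv"))
    zone_truth <- utils::read.csv(pth("zone_truth.csv"))
    fsets <- sv_feature_sets()
    rows <- list()
    fit_one <- function(target, X, y, fam, buffer) {
      fit <- fit_cv(X, y, fam, k = 5, seed = derive_seed(cfg$seed, target),
                    target_name = target, buffer_m = buffer)
      data.frame(target = target, method = fam, buffer_m = buffer,
                 rmse = fit$cv_rmse, r2 = fit$cv_r2, mae = fit$cv_mae,
                 n = fit$n, stringsAsFactors = FALSE)
    }
    m <- match(feats$zone_id, zone_truth$zone_id)
    for (target in c("trees", "sidewalk_length", "traffic_lights", "traffic_signs")) {
      y <- zone_truth[[target]][m]
      if (stats::sd(y) == 0) next
      for (fam in cfg$families)
        rows[[length(rows) + 1]] <- fit_one(
          target, feats[fsets[[target]]], y, fam, cfg$zone_radius_m)
    }
    ints <- truth$intersections
    for (target in c("pedestrians", "bicycles", "vehicles")) {
      r <- cfg$intersection_buffers[[target]]
      zones <- lapply(seq_len(nrow(ints)), function(i)
        build_zone(c(ints$x[i], ints$y[i]), r, "euclidean_disc",
                   zone_id = ints$id[i], kind = "intersection"))
      zf <- aggregate_zones(summaries, zones, points)
      mi <- match(zf$zone_id, ints$id)
      for (fam in cfg$families)
        rows[[length(rows) + 1]] <- fit_one(
          target, zf[fsets[[target]]], ints[[target]][mi], fam, r)
    }
    results <- do.call(rbind, rows)
    write_csv_stable(results, pth("results.csv"))
    manifest <- mark("model", pth("results.csv"))
  }

  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(manifest)
}
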
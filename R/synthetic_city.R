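# Synthetic-city generator: a perturbed street grid, ground truth (trees,
# sidewalks, intersection traffic, signs/lights) and per-image class-fraction
# summaries with the statistical structure the downstream analysis assumes,
# so every pipeline stage runs and is tested without external imagery.
#
# The generator deliberately encodes the two confounders observed with real
# imagery: parked cars make the car-pixel fraction *inversely* related to
# true traffic where parking prevalence is high, and paved rural shoulders
# produce false sidewalk signal on rural road segments. A "shift" block
# (higher parked-car prevalence, shoulder confusion, rescaled traffic
# definition) turns a config into a test city, emulating a two-city
# train/test design.
#
# Everything is a pure function of the config: each stage draws from an RNG
# seeded by a sub-seed derived from config$seed and the stage name.

#' Configuration for a synthetic city
#'
#' @param seed master integer seed; the entire city is a pure function of the
#'   config.
#' @param grid_n blocks per side of the street grid.
#' @param block_m block edge length, metres.
#' @param jitter_m Gaussian perturbation of interior grid vertices, metres.
#' @param arterial_every every k-th interior grid line is an arterial;
#'   boundary lines are rural.
#' @param tree_base_per_m baseline street-tree intensity (trees per metre of
#'   street).
#' @param tree_amp relative amplitude of the smooth spatial tree-intensity
#'   field.
#' @param sidewalk_prob_by_road_class named Bernoulli probabilities.
#' @param traffic_base baseline vehicle count at an intersection.
#' @param arterial_boost log-scale traffic boost per incident arterial.
#' @param parked_car_prevalence in `[0, 1]`; parked cars concentrate where
#'   traffic is low.
#' @param shoulder_confusion false sidewalk-pixel signal on rural segments
#'   (fraction of image area; 0 disables).
#' @param tree_corr_m correlation length of the tree-intensity field, metres.
#' @param noise_sd named list of per-image Gaussian noise SDs by channel
#'   (`vegetation`, `sidewalk`, `person`, `bicycle`, `car`, `road`, `sign`).
#' @param noise_field_sd named list of SDs for spatially correlated noise
#'   fields added per channel (currently `vegetation`); correlated
#'   measurement error survives zone aggregation, unlike per-image noise,
#'   and is what the population-R2 calibration adjusts.
#' @param noise_field_corr_m correlation length of the noise fields, metres.
#' @param influence_m radius within which ground objects are visible from a
#'   point (default 75, the typical detection range of street imagery).
#' @param shift optional named list of overrides producing a test city (e.g.
#'   `list(parked_car_prevalence = 0.9, shoulder_confusion = 0.03,
#'   traffic_rescale = 2)`).
#' @return A `city_config` object.
#' @export
city_config <- function(seed = 1L, grid_n = 8, block_m = 150, jitter_m = 10,
                        arterial_every = 4,
                        tree_base_per_m = 0.04, tree_amp = 0.8,
                        tree_corr_m = 800,
                        sidewalk_prob_by_road_class = c(residential = 0.95,
                                                        arterial = 0.70,
                                                        rural = 0.05),
                        traffic_base = 400, arterial_boost = 0.7,
                        parked_car_prevalence = 0.30,
                        shoulder_confusion = 0,
                        noise_sd = list(vegetation = 0.03, sidewalk = 0.001,
                                        person = 0.003, bicycle = 0.0015,
                                        car = 0.025, road = 0.03,
                                        sign = 0.0012),
                        noise_field_sd = list(vegetation = 0),
                        noise_field_corr_m = 800,
                        influence_m = 75,
                        shift = NULL) {
  stopifnot(grid_n >= 2, block_m > 0,
            all(sidewalk_prob_by_road_class >= 0 & sidewalk_prob_by_road_class <= 1),
            parked_car_prevalence >= 0, parked_car_prevalence <= 1,
            all(unlist(noise_sd) >= 0))
  cfg <- list(seed = as.integer(seed), grid_n = grid_n, block_m = block_m,
              jitter_m = jitter_m, arterial_every = arterial_every,
              tree_base_per_m = tree_base_per_m, tree_amp = tree_amp,
              tree_corr_m = tree_corr_m,
              noise_field_sd = noise_field_sd,
              noise_field_corr_m = noise_field_corr_m,
              sidewalk_prob_by_road_class = sidewalk_prob_by_road_class,
              traffic_base = traffic_base, arterial_boost = arterial_boost,
              parked_car_prevalence = parked_car_prevalence,
              shoulder_confusion = shoulder_confusion,
              noise_sd = noise_sd, influence_m = influence_m,
              traffic_rescale = 1, shift = shift)
  structure(cfg, class = "city_config")
}

#' Derive the shifted test-city configuration
#'
#' Applies the config's `shift` overrides (and a derived seed) to produce the
#' companion test city.
#' @param config a [city_config] with a non-`NULL` `shift`.
#' @return A new `city_config`.
#' @export
test_city_config <- function(config) {
  if (is.null(config$shift)) stopf("config has no shift block")
  out <- config
  for (nm in names(config$shift)) out[[nm]] <- config$shift[[nm]]
  out$shift <- NULL
  out$seed <- derive_seed(config$seed, "test_city")
  out
}

# Smooth random field: a sum of K Fourier modes with wavelengths around
# `corr_len`, unit variance, reproducible from the seed.
make_field <- function(seed, corr_len, K = 12) {
  with_seed(seed, {
    th <- stats::runif(K, 0, 2 * pi)
    lam <- corr_len * 2 * stats::runif(K, 0.6, 1.6)
    ph <- stats::runif(K, 0, 2 * pi)
  })
  ux <- cos(th); uy <- sin(th)
  amp <- sqrt(2 / K)
  function(x, y) {
    v <- 0
    for (k in seq_len(K))
      v <- v + amp * sin(2 * pi * (x * ux[k] + y * uy[k]) / lam[k] + ph[k])
    v
  }
}

city_fields <- function(config) {
  list(tree = make_field(derive_seed(config$seed, "field_tree"),
                         config$tree_corr_m),
       traffic = make_field(derive_seed(config$seed, "field_traffic"), 1000),
       ped = make_field(derive_seed(config$seed, "field_ped"), 500),
       bike = make_field(derive_seed(config$seed, "field_bike"), 500),
       parking = make_field(derive_seed(config$seed, "field_parking"), 700))
}

#' Generate the synthetic street network
#'
#' A perturbed `grid_n` x `grid_n` block grid: 2 * grid_n * (grid_n + 1)
#' segments. Boundary grid lines are rural, every `arterial_every`-th
#' interior line is an arterial, the rest are residential.
#'
#' @param config a [city_config].
#' @return A [street_network] in a local metric CRS.
#' @export
gen_network <- function(config) {
  n <- config$grid_n
  b <- config$block_m
  nodes <- array(0, dim = c(n + 1, n + 1, 2))
  with_seed(derive_seed(config$seed, "network"), {
    for (i in 0:n) for (j in 0:n) {
      interior <- i > 0 && i < n && j > 0 && j < n
      jit <- if (interior) stats::rnorm(2, 0, config$jitter_m) else c(0, 0)
      nodes[i + 1, j + 1, ] <- c(i * b, j * b) + jit
    }
  })
  line_class <- function(idx) {
    if (idx == 0 || idx == n) "rural"
    else if (idx %% config$arterial_every == 0) "arterial"
    else "residential"
  }
  segs <- list()
  for (j in 0:n) for (i in 0:(n - 1))   # horizontal, along line y = j
    segs[[length(segs) + 1]] <- list(
      segment_id = sprintf("h_%d_%d", i, j),
      polyline = rbind(nodes[i + 1, j + 1, ], nodes[i + 2, j + 1, ]),
      road_class = line_class(j))
  for (i in 0:n) for (j in 0:(n - 1))   # vertical, along line x = i
    segs[[length(segs) + 1]] <- list(
      segment_id = sprintf("v_%d_%d", i, j),
      polyline = rbind(nodes[i + 1, j + 1, ], nodes[i + 1, j + 2, ]),
      road_class = line_class(i))
  street_network(segs, crs_id = "local:meters")
}

#' Generate ground truth for a synthetic city
#'
#' Trees follow an inhomogeneous Poisson process along streets (intensity
#' `tree_base_per_m * (1 + tree_amp * field)`, clamped at 0); sidewalk
#' presence is Bernoulli by road class; intersection traffic is a
#' gravity-style log-normal intensity boosted by incident arterials; signs
#' and lights sit at intersections with class-dependent probability.
#'
#' @param network from [gen_network].
#' @param config the same [city_config].
#' @return List: `trees` (data.frame x, y), `sidewalks` (segment_id,
#'   road_class, sidewalk_truth), `intersections` (id, x, y, vehicles,
#'   pedestrians, bicycles, n_signs, n_lights), `expected_trees` (the
#'   analytic mean total of the tree process).
#' @export
gen_ground_truth <- function(network, config) {
  fields <- city_fields(config)
  step <- 5  # integration step, metres
  seg_int <- lapply(network$segments, function(s) {
    L <- s$length_m
    ss <- seq(step / 2, L, by = step)
    if (!length(ss)) ss <- L / 2
    xy <- t(vapply(ss, function(o) polyline_interpolate(s$polyline, o), numeric(2)))
    lam <- pmax(0, config$tree_base_per_m *
                  (1 + config$tree_amp * fields$tree(xy[, 1], xy[, 2])))
    w <- rep(step, length(ss)); w[length(w)] <- L - (length(ss) - 1) * step
    list(offsets = ss, lambda = lam, w = w, total = sum(lam * w))
  })
  expected_trees <- sum(vapply(seg_int, `[[`, 0, "total"))

  trees <- NULL
  sidewalk_truth <- logical(length(network$segments))
  with_seed(derive_seed(config$seed, "ground_truth"), {
    trees <- do.call(rbind, lapply(seq_along(network$segments), function(k) {
      si <- seg_int[[k]]
      ntot <- stats::rpois(1, si$total)
      if (ntot == 0) return(NULL)
      p <- si$lambda * si$w
      if (sum(p) == 0) return(NULL)
      bins <- sample(seq_along(si$offsets), ntot, replace = TRUE, prob = p)
      offs <- si$offsets[bins] + stats::runif(ntot, -si$w[bins] / 2, si$w[bins] / 2)
      xy <- t(vapply(offs, function(o)
        polyline_interpolate(network$segments[[k]]$polyline, o), numeric(2)))
      data.frame(x = xy[, 1], y = xy[, 2])
    }))
    probs <- config$sidewalk_prob_by_road_class
    sidewalk_truth <- vapply(network$segments, function(s)
      stats::runif(1) < probs[[s$road_class]], TRUE)
  })
  if (is.null(trees)) trees <- data.frame(x = numeric(), y = numeric())

  # intersections = grid nodes; incident arterial count from segment classes
  node_xy <- unique(do.call(rbind, lapply(network$segments, function(s)
    rbind(s$polyline[1, ], s$polyline[nrow(s$polyline), ]))))
  n_art <- vapply(seq_len(nrow(node_xy)), function(i) {
    p <- node_xy[i, ]
    sum(vapply(network$segments, function(s)
      s$road_class == "arterial" &&
        (sum((s$polyline[1, ] - p)^2) < 1e-6 ||
         sum((s$polyline[nrow(s$polyline), ] - p)^2) < 1e-6), TRUE))
  }, 0)
  fr <- fields$traffic(node_xy[, 1], node_xy[, 2])
  fp <- fields$ped(node_xy[, 1], node_xy[, 2])
  fb <- fields$bike(node_xy[, 1], node_xy[, 2])
  with_seed(derive_seed(config$seed, "traffic"), {
    vehicles <- config$traffic_rescale * config$traffic_base *
      exp(0.6 * fr + config$arterial_boost * n_art + stats::rnorm(nrow(node_xy), 0, 0.06))
    pedestrians <- config$traffic_rescale * 60 *
      exp(0.7 * fp + stats::rnorm(nrow(node_xy), 0, 0.2))
    bicycles <- config$traffic_rescale * 25 *
      exp(0.7 * fb + stats::rnorm(nrow(node_xy), 0, 0.25))
    p_sign <- pmin(1, 0.25 + 0.3 * n_art)
    n_signs <- stats::rbinom(nrow(node_xy), 4, p_sign)
    n_lights <- stats::rbinom(nrow(node_xy), 1, pmin(1, 0.05 + 0.35 * n_art))
  })
  intersections <- data.frame(
    id = sprintf("int%03d", seq_len(nrow(node_xy))),
    x = node_xy[, 1], y = node_xy[, 2],
    vehicles = vehicles, pedestrians = pedestrians, bicycles = bicycles,
    n_signs = n_signs, n_lights = n_lights, n_arterial = n_art,
    stringsAsFactors = FALSE)
  list(trees = trees,
       sidewalks = data.frame(
         segment_id = vapply(network$segments, `[[`, "", "segment_id"),
         road_class = vapply(network$segments, `[[`, "", "road_class"),
         sidewalk_truth = sidewalk_truth, stringsAsFactors = FALSE),
       intersections = intersections,
       expected_trees = expected_trees)
}

count_within <- function(px, py, qx, qy, radius) {
  if (!length(qx)) return(rep(0, length(px)))
  vapply(seq_along(px), function(i)
    sum((qx - px[i])^2 + (qy - py[i])^2 <= radius^2), 0)
}

# Noise-free per-point signals; the rendered summaries are these plus
# channel noise, co-normalized with a building/sky remainder.
point_signals <- function(points, truth, config) {
  fields <- city_fields(config)
  r <- config$influence_m
  trees75 <- count_within(points$x, points$y, truth$trees$x, truth$trees$y, r)
  # nearest intersection supplies the local traffic regime
  ints <- truth$intersections
  tnorm <- ints$vehicles / max(ints$vehicles)
  # local traffic regime: inverse-distance-squared average of intersections
  # within 450 m (a point mostly sees its segment's endpoints)
  traffic_norm <- vapply(seq_len(nrow(points)), function(i) {
    d2 <- (ints$x - points$x[i])^2 + (ints$y - points$y[i])^2
    near <- d2 <= 450^2
    if (!any(near)) near <- which.min(d2)
    w <- 1 / (d2[near] + 50^2)
    sum(w * tnorm[near]) / sum(w)
  }, 0)
  ped_norm <- (fields$ped(points$x, points$y) + 2) / 4
  bike_norm <- (fields$bike(points$x, points$y) + 2) / 4
  signs75 <- vapply(seq_len(nrow(points)), function(i) {
    near <- (ints$x - points$x[i])^2 + (ints$y - points$y[i])^2 <= r^2
    sum(ints$n_signs[near])
  }, 0)
  lights75 <- vapply(seq_len(nrow(points)), function(i) {
    near <- (ints$x - points$x[i])^2 + (ints$y - points$y[i])^2 <= r^2
    sum(ints$n_lights[near])
  }, 0)
  sw <- truth$sidewalks
  seg_i <- match(points$segment_id, sw$segment_id)
  sw_true <- sw$sidewalk_truth[seg_i]
  rural <- sw$road_class[seg_i] == "rural"
  # parking concentrates where traffic is low, modulated by a neighbourhood
  # parking-supply field of its own
  park_supply <- pmin(1, pmax(0, (fields$parking(points$x, points$y) + 2) / 4))
  parked_local <- config$parked_car_prevalence *
    (0.85 * (1 - traffic_norm) + 0.15 * park_supply)
  data.frame(
    point_id = points$point_id,
    trees75 = trees75,
    vegetation = stats::plogis(-2.2 + 0.04 * trees75),
    sidewalk = 0.08 * sw_true + config$shoulder_confusion * rural,
    person = 0.003 + 0.012 * ped_norm,
    bicycle = 0.0008 + 0.004 * bike_norm,
    rider = 0.0004 + 0.002 * bike_norm,
    car = 0.02 + 0.12 * traffic_norm + 0.22 * parked_local,
    road = 0.32 - 0.03 * traffic_norm,
    truck = 0.004 + 0.004 * traffic_norm,
    traffic_sign = 0.0035 * signs75,
    traffic_light = 0.006 * lights75,
    pole = 0.004 + 0.0012 * (signs75 + lights75),
    traffic_norm = traffic_norm,
    stringsAsFactors = FALSE)
}

#' Render per-image class-fraction summaries
#'
#' Four images (headings 0/90/180/270) per non-excluded point. Channel
#' signals follow the generator's links (vegetation: logistic in the local
#' tree count; sidewalk: positive where the segment truly has one, plus a
#' shoulder-confusion false signal on rural segments; car: parked-car plus
#' driving-traffic components; road: decreasing in traffic), each plus
#' Gaussian per-image noise, clipped to `[0, 1]` and co-normalized with a
#' building/sky remainder so the 19 fractions + void sum to 1.
#'
#' @param points sample points data.frame.
#' @param truth from [gen_ground_truth].
#' @param config the [city_config].
#' @return data.frame of summaries (one row per image) with the noise-free
#'   per-point signals attached as attribute `"signals"`.
#' @export
render_summaries <- function(points, truth, config) {
  pts <- points[!points$excluded, , drop = FALSE]
  sig <- point_signals(pts, truth, config)
  n_img <- nrow(pts) * 4L
  idx <- rep(seq_len(nrow(pts)), each = 4L)
  ns <- config$noise_sd
  noise <- function(sd_) if (sd_ > 0) stats::rnorm(n_img, 0, sd_) else numeric(n_img)
  nf_sd <- config$noise_field_sd$vegetation
  veg_field_noise <- if (!is.null(nf_sd) && nf_sd > 0)
    noise_field_values(pts, config) * nf_sd else numeric(nrow(pts))
  out <- NULL
  with_seed(derive_seed(config$seed, "render"), {
    clip01 <- function(v) pmin(1, pmax(0, v))
    vegetation <- clip01(sig$vegetation[idx] + veg_field_noise[idx] +
                           noise(ns$vegetation))
    sidewalk <- clip01(sig$sidewalk[idx] + noise(ns$sidewalk))
    person <- clip01(sig$person[idx] + noise(ns$person))
    bicycle <- clip01(sig$bicycle[idx] + noise(ns$bicycle))
    rider <- clip01(sig$rider[idx] + noise(ns$bicycle))
    car <- clip01(sig$car[idx] + noise(ns$car))
    road <- clip01(sig$road[idx] + noise(ns$road))
    truck <- clip01(sig$truck[idx] + noise(0.006))
    traffic_sign <- clip01(sig$traffic_sign[idx] + noise(ns$sign))
    traffic_light <- clip01(sig$traffic_light[idx] + noise(ns$sign))
    pole <- clip01(sig$pole[idx] + noise(ns$sign))
    out <- data.frame(
      point_id = rep(pts$point_id, each = 4L),
      heading_deg = rep(c(0L, 90L, 180L, 270L), times = nrow(pts)),
      road = road, sidewalk = sidewalk, building = 0, wall = 0.008,
      fence = 0.008, pole = pole, traffic_light = traffic_light,
      traffic_sign = traffic_sign, vegetation = vegetation, terrain = 0.03,
      sky = 0, person = person, rider = rider, car = car, truck = truck,
      bus = 0.002, train = 0, motorcycle = 0.001, bicycle = bicycle,
      void_fraction = 0, stringsAsFactors = FALSE)
  })
  # co-normalize: cap the named classes at 0.95 of the area, then split the
  # remainder between building and sky so conservation holds exactly
  cls <- sv_classes()
  tot <- Reduce(`+`, out[cls])
  over <- tot > 0.95
  if (any(over)) {
    sc <- ifelse(over, 0.95 / tot, 1)
    for (c in cls) out[[c]] <- out[[c]] * sc
    tot <- pmin(tot, 0.95)
  }
  rem <- 1 - tot
  out$building <- out$building + 0.4 * rem
  out$sky <- out$sky + 0.6 * rem
  out <- collapse_summary_frame(out)
  attr(out, "signals") <- sig
  out
}

#' Rasterize a summary row into a label mask
#'
#' Builds a `size` x `size` mask whose class pixel counts match the requested
#' fractions to within one pixel (largest-remainder apportionment), so
#' [summarize_mask] recovers the summary to within `1 / size^2`.
#'
#' @param summary_row one row of a summaries data.frame (or named list).
#' @param size mask side length in pixels (default 64).
#' @return Integer label matrix.
#' @export
render_mask <- function(summary_row, size = 64) {
  s <- as.list(summary_row)
  fr <- c(unlist(s[sv_classes()]), void = s$void_fraction)
  npix <- size * size
  ideal <- fr * npix
  base <- floor(ideal)
  shortfall <- npix - sum(base)
  if (shortfall > 0) {
    extra <- order(ideal - base, decreasing = TRUE)[seq_len(shortfall)]
    base[extra] <- base[extra] + 1
  }
  labels <- c(0:18, sv_void)
  matrix(rep(labels, times = base), nrow = size, ncol = size)
}

#' Generate a complete synthetic city
#'
#' Network, ground truth, sample points and image summaries in one call; the
#' whole result is a pure function of the config.
#'
#' @param config a [city_config].
#' @param spacing_m sampling interval (default 150).
#' @return List `config`, `network`, `truth`, `points`, `summaries`.
#' @export
synth_city <- function(config, spacing_m = 150) {
  network <- gen_network(config)
  truth <- gen_ground_truth(network, config)
  points <- sample_points(network, spacing_m)
  summaries <- render_summaries(points, truth, config)
  list(config = config, network = network, truth = truth,
       points = points, summaries = summaries)
}

#' Draw zone centroids inside the city
#'
#' Uniformly random centroids in the city interior (default margin of one
#' block from the edge), reproducible from the config seed.
#' @param config a [city_config].
#' @param n number of centroids.
#' @param margin_m minimum distance from the city edge.
#' @return data.frame `zone_id`, `x`, `y`.
#' @export
gen_zone_centroids <- function(config, n, margin_m = config$block_m) {
  W <- config$grid_n * config$block_m
  m <- margin_m
  with_seed(derive_seed(config$seed, "centroids"), {
    data.frame(zone_id = sprintf("pc%04d", seq_len(n)),
               x = stats::runif(n, m, W - m),
               y = stats::runif(n, m, W - m), stringsAsFactors = FALSE)
  })
}

#' Count true trees inside a zone
#' @param trees data.frame `x`, `y`.
#' @param zone a zone.
#' @return Integer count.
#' @export
zone_tree_count <- function(trees, zone) {
  sum(zone_contains(zone, trees$x, trees$y))
}

#' Values of the correlated vegetation noise field at points
#'
#' The unit-variance field realization that [render_summaries] scales by
#' `noise_field_sd$vegetation`; exposed so the calibration below can measure
#' its zone-level attenuation.
#' @param points sample points.
#' @param config the [city_config].
#' @return Numeric vector, one value per point.
#' @export
noise_field_values <- function(points, config) {
  f <- make_field(derive_seed(config$seed, "noise_field_vegetation"),
                  config$noise_field_corr_m)
  f(points$x, points$y)
}

#' Noise-field SD that yields a target zone-level population R2
#'
#' For a linear readout of a noise-free zone signal, adding zone-level noise
#' of variance `var(signal) * (1/r2 - 1)` gives population R2 = `r2`.
#' Because the correlated noise field is attenuated by zone averaging, the
#' required field SD is the zone-level SD divided by the measured
#' attenuation: the SD across zones of the zone-mean of the unit field
#' realization that rendering will use.
#'
#' @param zone_signal noise-free zone-level signal values (one per zone).
#' @param points sample points.
#' @param zones list of zones (same order as `zone_signal`).
#' @param config the [city_config].
#' @param r2_target desired population R2.
#' @return SD to set as `noise_field_sd$vegetation`.
#' @export
noise_sd_for_r2 <- function(zone_signal, points, zones, config, r2_target) {
  u <- noise_field_values(points, config)
  zu <- vapply(zones, function(z)
    mean(u[zone_contains(z, points$x, points$y)]), 0)
  atten <- stats::sd(zu)
  stats::sd(zone_signal) * sqrt(1 / r2_target - 1) / atten
}

#' Synthesize an intersection target with a known spatial scale
#'
#' The target at each intersection is the mean of the noise-free per-point
#' person signal over the points within `scale_m`, plus a little noise:
#' a target genuinely "generated at `scale_m` scale", used to check that the
#' buffer sweep recovers the generative scale.
#'
#' @param points sample points.
#' @param signals the `"signals"` attribute of [render_summaries] output.
#' @param intersections data.frame `id`, `x`, `y`.
#' @param scale_m generative radius, metres.
#' @param noise_frac target noise SD as a fraction of the signal SD.
#' @param seed integer seed.
#' @return data.frame `id`, `value`.
#' @export
gen_scaled_target <- function(points, signals, intersections, scale_m = 500,
                              noise_frac = 0.1, seed = 1L) {
  sig <- signals$person[match(points$point_id, signals$point_id)]
  val <- vapply(seq_len(nrow(intersections)), function(i) {
    d2 <- (points$x - intersections$x[i])^2 + (points$y - intersections$y[i])^2
    mean(sig[d2 <= scale_m^2])
  }, 0)
  with_seed(seed, {
    val <- val + stats::rnorm(length(val), 0, noise_frac * stats::sd(val))
  })
  data.frame(id = intersections$id, value = val, stringsAsFactors = FALSE)
}
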
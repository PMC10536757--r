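test_that("the L1 diamond has the right vertices and closed membership", {
  z <- build_zone(c(0, 0), 500, "l1_diamond")
  expect_equal(sort(abs(z$polygon[, 1]) + abs(z$polygon[, 2])),
               rep(500, 4))
  expect_true(zone_contains(z, 0, 0))
  expect_false(zone_contains(z, 300, 300))   # L1 = 600 > 500
  expect_true(zone_contains(z, 250, 250))    # exactly on the boundary
  expect_true(zone_contains(z, 500, 0))
})

test_that("diamond membership equals the direct |dx|+|dy| predicate on 10k points", {
  set.seed(21)
  z <- build_zone(c(120, -40), 500, "l1_diamond")
  x <- runif(10000, -800, 1000); y <- runif(10000, -900, 900)
  expect_identical(zone_contains(z, x, y),
                   abs(x - 120) + abs(y + 40) <= 500)
})

test_that("disc membership is the Euclidean predicate", {
  z <- build_zone(c(0, 0), 100, "euclidean_disc")
  set.seed(2)
  x <- runif(2000, -150, 150); y <- runif(2000, -150, 150)
  expect_identical(zone_contains(z, x, y), x^2 + y^2 <= 100^2)
})

test_that("network buffers cover exactly the reachable street length", {
  # straight isolated street: 1500 m east-west, anchor mid-street
  net <- street_network(list(list(
    segment_id = "s", polyline = rbind(c(0, 0), c(1500, 0)))),
    crs_id = "local:meters")
  z <- build_zone(c(750, 10), 500, "network", network = net)
  iv <- z$covered[["s"]]
  expect_equal(iv[[1]], c(250, 1250))  # 500 m each way
  expect_error(build_zone(c(750, 600), 500, "network", network = net),
               "farther")
})

test_that("network-buffer coverage never exceeds the radius (shortest-path oracle)", {
  cfg <- city_config(seed = 5, grid_n = 4, block_m = 150)
  net <- gen_network(cfg)
  expect_length(net$segments, 40)
  anchor <- c(290, 310)
  r <- 400
  z <- build_zone(anchor, r, "network", network = net)
  # independent oracle: Bellman-Ford over the endpoint graph plus the anchor
  key <- function(p) sprintf("%.6f,%.6f", p[1], p[2])
  ends <- lapply(net$segments, function(s)
    list(u = key(s$polyline[1, ]), v = key(s$polyline[2, ]), w = s$length_m))
  verts <- unique(unlist(lapply(ends, function(e) c(e$u, e$v))))
  near <- streetscape:::nearest_on_network(net, anchor)
  host <- streetscape:::network_segment(net, near$segment_id)
  edges <- do.call(rbind, lapply(ends, function(e)
    c(match(e$u, verts), match(e$v, verts), e$w)))
  src <- length(verts) + 1
  edges <- rbind(edges,
                 c(match(key(host$polyline[1, ]), verts), src, near$offset),
                 c(match(key(host$polyline[2, ]), verts), src,
                   host$length_m - near$offset))
  d <- oracle_shortest_paths(edges, src, src)
  for (sid in names(z$covered)) {
    s <- streetscape:::network_segment(net, sid)
    du <- d[match(key(s$polyline[1, ]), verts)]
    dv <- d[match(key(s$polyline[2, ]), verts)]
    for (iv in z$covered[[sid]]) {
      # every covered arc position must be within r by the oracle's distances
      for (t in seq(iv[1], iv[2], length.out = 5)) {
        reach <- min(du + t, dv + (s$length_m - t))
        if (sid == near$segment_id) reach <- min(reach, abs(t - near$offset))
        expect_lte(reach, r + 1e-6)
      }
    }
  }
})

test_that("zone aggregation is the unweighted image mean and de-duplicates", {
  set.seed(13)
  pts <- data.frame(point_id = sprintf("p%02d", 1:6),
                    segment_id = "s", offset_m = 1:6,
                    x = runif(6, -100, 100), y = runif(6, -100, 100),
                    excluded = FALSE)
  rows <- do.call(rbind, lapply(1:6, function(i)
    rbind(make_summary_row(pts$point_id[i], 0,
                           list(vegetation = runif(1, 0, 0.5))),
          make_summary_row(pts$point_id[i], 90,
                           list(vegetation = runif(1, 0, 0.5))))))
  z <- build_zone(c(0, 0), 500, "l1_diamond", zone_id = "z")
  fv <- aggregate_zone(rows, z, pts)
  expect_equal(fv$n_images, 12)
  expect_equal(fv$vegetation, mean(rows$vegetation), tolerance = 1e-12)
  # duplicated (point, heading) rows do not change the vector
  fv2 <- aggregate_zone(rbind(rows, rows[3, ]), z, pts)
  expect_equal(fv2$vegetation, fv$vegetation, tolerance = 1e-15)
  expect_equal(fv2$n_images, fv$n_images)
  # single image: identity
  fv1 <- aggregate_zone(rows[1, ], z, pts[1, ])
  expect_equal(fv1$vegetation, rows$vegetation[1])
  # empty zone is flagged missing
  far <- build_zone(c(5000, 5000), 10, "l1_diamond", zone_id = "far")
  expect_warning(out <- aggregate_zone(rows, far, pts), "missing")
  expect_null(out)
})

test_that("excluded points do not contribute images", {
  pts <- data.frame(point_id = c("a", "b"), segment_id = "s",
                    offset_m = c(1, 2), x = c(0, 1), y = c(0, 1),
                    excluded = c(TRUE, FALSE))
  rows <- rbind(make_summary_row("a", 0, list(vegetation = 1)),
                make_summary_row("b", 0, list(vegetation = 0.5)))
  z <- build_zone(c(0, 0), 100, "l1_diamond")
  fv <- aggregate_zone(rows, z, pts)
  expect_equal(fv$n_images, 1)
  expect_equal(fv$vegetation, 0.5)
})

test_that("sidewalk segment labels follow the any-image-exceeds rule", {
  pts <- data.frame(point_id = c("p1", "p2", "p3"),
                    segment_id = c("s1", "s1", "s2"),
                    offset_m = c(10, 20, 10), x = 1:3, y = 0,
                    excluded = FALSE)
  sm <- rbind(make_summary_row("p1", 0, list(sidewalk = 0.001)),
              make_summary_row("p1", 90, list(sidewalk = 0.03)),
              make_summary_row("p2", 0, list(sidewalk = 0)),
              make_summary_row("p3", 0, list(sidewalk = 0)))
  lab <- sidewalk_segment_labels(pts, sm, tau = 0.01)
  expect_true(lab$sidewalk_pred[lab$segment_id == "s1"])
  expect_false(lab$sidewalk_pred[lab$segment_id == "s2"])
  # tau = 0: any sidewalk pixel (fraction >= 0 holds everywhere) counts
  lab0 <- sidewalk_segment_labels(pts, sm, tau = 1e-9)
  expect_true(lab0$sidewalk_pred[lab0$segment_id == "s1"])
  expect_false(lab0$sidewalk_pred[lab0$segment_id == "s2"])
  # a segment with no imagery gets a missing label
  pts2 <- rbind(pts, data.frame(point_id = "p4", segment_id = "s3",
                                offset_m = 1, x = 9, y = 9, excluded = TRUE))
  lab2 <- sidewalk_segment_labels(pts2, sm, tau = 0.01)
  expect_true(is.na(lab2$sidewalk_pred[lab2$segment_id == "s3"]))
})

test_that("sidewalk length clips positively labelled segments to the zone", {
  net <- street_network(list(
    list(segment_id = "in", polyline = rbind(c(-100, 0), c(100, 0))),
    list(segment_id = "half", polyline = rbind(c(400, 0), c(600, 0))),
    list(segment_id = "neg", polyline = rbind(c(0, 50), c(50, 50)))),
    crs_id = "local:meters")
  z <- build_zone(c(0, 0), 500, "l1_diamond")
  labels <- data.frame(segment_id = c("in", "half", "neg"),
                       sidewalk_pred = c(TRUE, TRUE, FALSE))
  expect_equal(sidewalk_length_per_zone(net, labels, z), 200 + 100)
  labels$sidewalk_pred <- FALSE
  expect_equal(sidewalk_length_per_zone(net, labels, z), 0)
})

test_that("clipped sidewalk length is monotone in the zone radius", {
  cfg <- city_config(seed = 3, grid_n = 5)
  net <- gen_network(cfg)
  labels <- data.frame(
    segment_id = vapply(net$segments, `[[`, "", "segment_id"),
    sidewalk_pred = TRUE)
  lens <- vapply(seq(100, 900, by = 100), function(r)
    sidewalk_length_per_zone(net, labels,
                             build_zone(c(375, 375), r, "l1_diamond")), 0)
  expect_true(all(diff(lens) >= -1e-9))
  # disc clipping agrees with a fine-grained numeric oracle on one segment
  z <- build_zone(c(40, 10), 120, "euclidean_disc")
  seg <- net$segments[[1]]
  step_oracle <- {
    tt <- seq(0, seg$length_m, by = 0.01)
    xy <- t(vapply(tt, function(o)
      streetscape:::polyline_interpolate(seg$polyline, o), numeric(2)))
    sum(sqrt((xy[, 1] - 40)^2 + (xy[, 2] - 10)^2) <= 120) * 0.01
  }
  expect_equal(streetscape:::clip_segment_length(z, seg), step_oracle,
               tolerance = 0.05)
})
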
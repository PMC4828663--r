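test_that("PVI rings disconnect the sleeve from the LA body", {
  m <- la_mesh_coarse()
  ring <- pvi_ring(m, "RSPV")
  expect_gt(length(ring$elements), 0)
  keep <- setdiff(seq_len(nrow(m$triangles)), ring$elements)
  memb <- atrialab:::subset_components(m, keep)
  sleeve <- intersect(which(m$region == "RSPV"), keep)
  body <- intersect(which(m$region == "LA_body"), keep)
  expect_length(intersect(unique(memb[sleeve]), unique(memb[body])), 0)
  expect_error(pvi_ring(m, "RSPV", width_mm = 0), "positive")
  expect_error(pvi_ring(m, "nope"), "unknown")
})

test_that("paced PV sleeve cannot excite the body after PVI", {
  m <- build_la_surface(la_geometry_config(edge_length_mm = 1.2,
                                           size_mm = c(40, 40)))
  ring <- pvi_ring(m, "LIPV", width_mm = 2.5)
  cond <- apply_lesion(conductivity_field(m), ring)
  sys <- monodomain_system(m, cond)
  rec <- simulate_tissue(sys, init_tissue_state(sys), 0, 120,
                         list(stimulus(1, pv_sleeve_nodes(m, "LIPV"))),
                         dt_ms = 0.05)
  lat <- activation_times(rec)$lat
  body_nodes <- setdiff(seq_len(nrow(m$nodes)),
                        unique(as.vector(m$triangles[
                          m$region %in% c("LIPV"), ])))
  ost <- m$config$ostia
  k <- match("LIPV", ost$label)
  far <- body_nodes[sqrt((m$nodes[body_nodes, 1] - ost$x[k])^2 +
                         (m$nodes[body_nodes, 2] - ost$y[k])^2) >
                      ost$radius[k] + 8]
  expect_true(all(is.na(lat[far])))
})

test_that("geodesic lines are near-straight on a flat sheet", {
  m <- sheet_20()
  l <- geodesic_line(m, c(2, 2), c(18, 16), width_mm = 2)
  expect_gt(length(l$elements), 0)
  direct <- sqrt(sum((c(18, 16) - c(2, 2))^2))
  expect_lt(abs(attr(l, "path_length_mm") - direct) / direct, 0.1)
  # a band at least one element wide even for sub-element widths
  thin <- geodesic_line(m, c(2, 10), c(18, 10), width_mm = 0.2)
  expect_gt(length(thin$elements), 10)
  expect_error(geodesic_line(m, c(2, 2), c(18, 16), width_mm = 0),
               "positive")
})

test_that("roof line between PVI rings separates the body above and below", {
  # superior veins near the lateral borders, as on the atrial roof, so the
  # PVI rings abut the boundary and the roof line completes the barrier
  cfg <- la_geometry_config(
    size_mm = c(40, 40), edge_length_mm = 1,
    ostia = data.frame(label = c("LSPV", "RSPV"), x = c(9, 31),
                       y = 28, radius = 4),
    laa_center = c(-100, -100), laa_radius_mm = 0)
  m <- build_la_surface(cfg)
  r1 <- pvi_ring(m, "RSPV"); r2 <- pvi_ring(m, "LSPV")
  roof <- geodesic_line(m, c(16, 28), c(24, 28), width_mm = 2,
                        name = "roof")
  les <- unique(c(r1$elements, r2$elements, roof$elements))
  keep <- setdiff(seq_len(nrow(m$triangles)), les)
  memb <- atrialab:::subset_components(m, keep)
  cent <- (m$nodes[m$triangles[, 1], ] + m$nodes[m$triangles[, 2], ] +
             m$nodes[m$triangles[, 3], ]) / 3
  above <- keep[cent[keep, 2] > 38 & m$region[keep] == "LA_body"]
  below <- keep[cent[keep, 2] < 18 & m$region[keep] == "LA_body"]
  expect_gt(length(above), 0)
  expect_gt(length(below), 0)
  # the corridor above the roof line is disconnected from the body below
  expect_length(intersect(unique(memb[above]), unique(memb[below])), 0)
})

test_that("lesion shapes respect enclosure and perforation semantics", {
  m <- sheet_mesh(c(40, 40), 0.75)
  cent <- (m$nodes[m$triangles[, 1], ] + m$nodes[m$triangles[, 2], ] +
             m$nodes[m$triangles[, 3], ]) / 3
  solid <- lesion_shape(m, c(20, 20), "circle", 1.5)
  keep <- setdiff(seq_len(nrow(m$triangles)), solid$elements)
  memb <- atrialab:::subset_components(m, keep)
  inside <- keep[sqrt((cent[keep, 1] - 20)^2 + (cent[keep, 2] - 20)^2) < 5]
  outside <- keep[sqrt((cent[keep, 1] - 20)^2 +
                       (cent[keep, 2] - 20)^2) > 12]
  expect_length(intersect(unique(memb[inside]), unique(memb[outside])), 0)
  # perforated circle keeps the tissue globally connected
  perf <- lesion_shape(m, c(20, 20), "perforated_circle", 1.5)
  expect_lt(length(perf$elements), length(solid$elements))
  keep2 <- setdiff(seq_len(nrow(m$triangles)), perf$elements)
  memb2 <- atrialab:::subset_components(m, keep2)
  expect_equal(length(unique(memb2[keep2])), 1)
  # cross arms have the configured length (within one edge length)
  cr <- lesion_shape(m, c(20, 20), "cross", 1.5)
  xr <- range(cent[cr$elements, 1])
  yr <- range(cent[cr$elements, 2])
  expect_lt(abs(diff(xr) - 15), 2 * mean(m$edge_length))
  expect_lt(abs(diff(yr) - 15), 2 * mean(m$edge_length))
  expect_error(lesion_shape(m, c(20, 20), "circle", 2), "0.5, 1.5")
  expect_warning(lesion_shape(m, c(3, 3), "line", 1.5), "clipped")
})

test_that("density-guided placement picks maxima with documented tie-breaks", {
  m <- la_mesh_coarse()
  cent <- (m$nodes[m$triangles[, 1], ] + m$nodes[m$triangles[, 2], ] +
             m$nodes[m$triangles[, 3], ]) / 3
  dm <- structure(list(density = numeric(nrow(m$triangles)),
                       counts = NULL, radius_mm = 5), class = "density_map")
  el <- which(m$subdivision == 2)[25]
  dm$density[el] <- 1
  expect_equal(place_by_density(dm, m, 2), cent[el, 1:2])
  # tie: lowest element index wins
  el_b <- which(m$subdivision == 2)[50]
  dm$density[el_b] <- 1
  expect_equal(place_by_density(dm, m, 2), cent[min(el, el_b), 1:2])
  # all-zero density: geometric centroid, with a warning
  expect_warning(ctr <- place_by_density(dm, m, 5), "centroid")
  sub5 <- which(m$subdivision == 5)
  expect_equal(ctr, colMeans(cent[sub5, 1:2]), tolerance = 1e-9)
})

test_that("streamlines follow analytic activation fields", {
  m <- sheet_mesh(c(40, 40), 1)
  # planar LAT: constant gradient along x -> parallel straight lines
  lat <- m$nodes[, 1] / 0.5
  am <- structure(list(lat = lat, crossings = NULL, threshold_mv = -40),
                  class = "activation_map")
  lines <- streamline_lines(m, am, n_lines = 4, isochrone_offset_ms = 10)
  paths <- attr(lines, "paths")
  expect_length(lines, 4)
  for (p in paths) {
    expect_lt(diff(range(p[, 2])), 2)        # straight (constant y)
    expect_gte(max(p[, 1]), 39.9)            # reaches the far boundary
  }
  ys <- sort(vapply(paths, function(p) mean(p[, 2]), numeric(1)))
  expect_lt(diff(range(diff(ys))), 2)        # evenly spaced
  # pairwise non-intersection
  for (a in 1:3) for (b in (a + 1):4) {
    da <- min(abs(outer(paths[[a]][, 2], paths[[b]][, 2], "-")) +
                abs(outer(paths[[a]][, 1], paths[[b]][, 1], "-")))
    expect_gt(da, 0.5)
  }
  # radial LAT from a point source -> radial spokes
  ctr <- c(20, 20)
  lat_r <- sqrt((m$nodes[, 1] - ctr[1])^2 + (m$nodes[, 2] - ctr[2])^2) / 0.5
  am_r <- structure(list(lat = lat_r, crossings = NULL,
                         threshold_mv = -40), class = "activation_map")
  spokes <- streamline_lines(m, am_r, n_lines = 6,
                             isochrone_offset_ms = 10)
  for (p in attr(spokes, "paths")) {
    # each step moves away from the centre monotonically
    r <- sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
    expect_true(all(diff(r) > 0))
  }
  expect_error(streamline_lines(m, am, n_lines = 1), ">= 2")
})

test_that("lane count grows and lane width shrinks with more lines", {
  m <- sheet_mesh(c(40, 40), 1)
  lat <- m$nodes[, 1] / 0.5
  am <- structure(list(lat = lat, crossings = NULL, threshold_mv = -40),
                  class = "activation_map")
  n_seq <- c(2, 4, 6, 8)
  lanes <- lapply(n_seq, function(n) {
    ll <- streamline_lines(m, am, n_lines = n)
    streamline_lanes(m, ll, am)
  })
  counts <- vapply(lanes, `[[`, numeric(1), "n_lanes")
  widths <- vapply(lanes, `[[`, numeric(1), "max_width_mm")
  expect_true(all(counts >= n_seq - 1))
  expect_true(all(diff(counts) >= 0))
  expect_true(all(diff(widths) <= 0.5))  # non-increasing (0.5 mm jitter)
})
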
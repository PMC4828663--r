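# Shared fixtures: meshes are cached per test run (building them is the
# dominant cost of many tests).

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# default synthetic LA at 1 mm (fast): full geometry with ostia
la_mesh_coarse <- function() {
  fixture("la_1mm", function()
    build_la_surface(la_geometry_config(edge_length_mm = 1)))
}

# plain 20 x 20 mm sheet at 1 mm
sheet_20 <- function() {
  fixture("sheet20", function() sheet_mesh(c(20, 20), 1))
}

# 64 x 64 unit-spacing sheet for PS detector oracle tests
sheet_64 <- function() {
  fixture("sheet64", function() sheet_mesh(c(64, 64), 1))
}

# analytic multi-vortex phase field evaluated at points (k x >=2 matrix):
# sum over vortices of chirality * atan2(y - cy, x - cx) + phase offset
vortex_phase <- function(pts, centers, chirality, offset = 0) {
  ph <- rep(offset, nrow(pts))
  for (v in seq_len(nrow(centers))) {
    ph <- ph + chirality[v] * atan2(pts[, 2] - centers[v, 2],
                                    pts[, 1] - centers[v, 1])
  }
  (ph + pi) %% (2 * pi) - pi
}

# random vortex placements with a minimum pairwise separation (the
# detector and oracle are only well posed for resolved singularities)
random_vortices <- function(k, lo, hi, min_sep = 6) {
  repeat {
    ctr <- cbind(runif(k, lo, hi), runif(k, lo, hi))
    if (k == 1 || min(dist(ctr)) >= min_sep) return(ctr)
  }
}

# brute-force winding number of the analytic field around a triangle:
# sample M points along the triangle perimeter and sum wrapped increments
brute_winding <- function(tri_pts, centers, chirality, M = 60) {
  per <- rbind(tri_pts, tri_pts[1, ])
  samp <- NULL
  for (s in 1:3) {
    w <- seq(0, 1, length.out = M %/% 3 + 1)[-(M %/% 3 + 1)]
    samp <- rbind(samp, cbind(per[s, 1] + w * (per[s + 1, 1] - per[s, 1]),
                              per[s, 2] + w * (per[s + 1, 2] - per[s, 2])))
  }
  ph <- vortex_phase(samp, centers, chirality)
  d <- diff(c(ph, ph[1]))
  d <- d - 2 * pi * round(d / (2 * pi))
  round(sum(d) / (2 * pi))
}

# synthetic recording: given per-node activation time series generator,
# build frames matrix with a stylized action potential pulse train
pulse_recording <- function(act_times_per_node, t_end, record_dt = 1,
                            apd = 120) {
  times <- seq(0, t_end, by = record_dt)
  n <- length(act_times_per_node)
  frames <- matrix(-80, n, length(times))
  for (i in seq_len(n)) {
    for (a in act_times_per_node[[i]]) {
      up <- times >= a & times < a + apd
      frames[i, up] <- 20 - 100 * (times[up] - a) / apd
    }
  }
  structure(list(times = times, frames = frames, state = NULL,
                 stim_times = numeric(0), dt = record_dt,
                 record_dt = record_dt, ok = TRUE),
            class = "tissue_recording")
}

# 1D cable monodomain system (for conduction-velocity oracles): n nodes at
# spacing h_mm with isotropic diffusion D mm^2/ms
cable_system <- function(n, h_mm, sigma_sm = 0.22, paf_remodeled = TRUE) {
  D <- sigma_sm / 1.4
  main <- rep(2 * D / h_mm, n)
  main[c(1, n)] <- D / h_mm
  K <- Matrix::bandSparse(n, n, k = -1:1,
                          diagonals = list(rep(-D / h_mm, n - 1), main,
                                           rep(-D / h_mm, n - 1)))
  params <- vapply(c("LA_body", "PV", "LAA"), function(cl)
    make_region_params(cl, paf_remodeled = paf_remodeled), numeric(7))
  structure(list(mesh = NULL, K = methods::as(K, "CsparseMatrix"),
                 M = rep(h_mm, n), params = params,
                 region_idx = rep(0L, n),
                 classes = c("LA_body", "PV", "LAA"),
                 conductivity = NULL, paf_remodeled = paf_remodeled),
            class = "monodomain_system")
}

cable_state <- function(n) {
  y0 <- crn_initial_state()
  matrix(rep(as.numeric(y0), each = n), nrow = n)
}
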
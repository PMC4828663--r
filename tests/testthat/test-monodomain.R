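test_that("diffusion operator conserves constants and is symmetric", {
  m <- sheet_20()
  ops <- assemble_diffusion(m, conductivity_field(m))
  expect_lt(max(abs(Matrix::rowSums(ops$K))), 1e-10)
  expect_lt(max(abs(ops$K - Matrix::t(ops$K))), 1e-12)
  v <- rep(3.7, nrow(m$nodes))
  expect_lt(max(abs(as.vector(ops$K %*% v))), 1e-9)
  # lumped mass sums to the total surface area
  expect_equal(sum(ops$M), sum(triangle_areas(m)), tolerance = 1e-9)
})

test_that("quiescent tissue is a fixed point of the stepper", {
  m <- sheet_20()
  sys <- monodomain_system(m)
  # let the remodeled cells settle from the published baseline state, then
  # require quiescence to sub-0.01 mV over 1000 further steps
  settled <- simulate_tissue(sys, init_tissue_state(sys), 0, 300,
                             dt_ms = 0.02, record_dt = 100)$state
  rec <- simulate_tissue(sys, settled, 300, 320, dt_ms = 0.02)
  drift <- abs(rec$frames[, ncol(rec$frames)] - rec$frames[, 1])
  expect_lt(max(drift), 0.01)
})

test_that("zero conductivity decouples nodes to the single-cell limit", {
  m <- sheet_mesh(c(6, 6), 1)
  cond <- conductivity_field(m, sigma_l = 0, sigma_t = 0, floor_sm = 0)
  sys <- monodomain_system(m, cond)
  st <- init_tissue_state(sys)
  all_nodes <- seq_len(nrow(m$nodes))
  rec <- simulate_tissue(sys, st, 0, 300,
                         list(stimulus(0, all_nodes, 2, -30)),
                         dt_ms = 0.02, record_dt = 0.5, use_table = FALSE)
  ref <- pace_single_cell(make_region_params("LA_body"), 300, 1,
                          dt_ms = 0.02, record_dt = 0.5)
  w <- seq_len(min(ncol(rec$frames), length(ref$Vm)))
  expect_lt(max(abs(rec$frames[5, w] - ref$Vm[w])), 1e-6)
})

test_that("tabulated kinetics agree with exact kinetics in tissue", {
  m <- sheet_mesh(c(10, 6), 1)
  sys <- monodomain_system(m)
  st <- init_tissue_state(sys)
  stim <- list(stimulus(1, which(m$nodes[, 1] < 1)))
  r1 <- simulate_tissue(sys, st, 0, 40, stim, dt_ms = 0.02,
                        use_table = TRUE)
  r2 <- simulate_tissue(sys, st, 0, 40, stim, dt_ms = 0.02,
                        use_table = FALSE)
  expect_lt(max(abs(r1$frames - r2$frames)), 0.5)
})

test_that("planar conduction velocity matches a fine 1D cable within 10%", {
  # 2D sheet at 0.25 mm
  m <- sheet_mesh(c(16, 5), 0.25)
  sys <- monodomain_system(m)
  rec <- simulate_tissue(sys, init_tissue_state(sys), 0, 40,
                         list(stimulus(1, which(m$nodes[, 1] < 0.6))),
                         dt_ms = 0.02)
  lat <- activation_times(rec)$lat
  pa <- which.min((m$nodes[, 1] - 4)^2 + (m$nodes[, 2] - 2.5)^2)
  pb <- which.min((m$nodes[, 1] - 12)^2 + (m$nodes[, 2] - 2.5)^2)
  cv2d <- (m$nodes[pb, 1] - m$nodes[pa, 1]) / (lat[pb] - lat[pa])
  # 1D cable oracle at 0.1 mm
  n <- 161; h <- 0.1
  cs <- cable_system(n, h)
  recc <- simulate_tissue(cs, cable_state(n), 0, 40,
                          list(stimulus(1, 1:6)), dt_ms = 0.02)
  latc <- activation_times(recc)$lat
  cv1d <- (120 - 40) * h / (latc[120] - latc[40])
  expect_lt(abs(cv2d - cv1d) / cv1d, 0.10)
})

test_that("anisotropy gives CV ratio ~ sqrt(sigma_l/sigma_t)", {
  run_cv <- function(sz, axis) {
    m <- sheet_mesh(sz, 0.25)  # fibers along x
    sys <- monodomain_system(m)
    which_ax <- if (axis == "x") 1 else 2
    stim_nodes <- which(m$nodes[, which_ax] < 0.6)
    rec <- simulate_tissue(sys, init_tissue_state(sys), 0,
                           if (axis == "x") 60 else 130,
                           list(stimulus(1, stim_nodes)), dt_ms = 0.02)
    lat <- activation_times(rec)$lat
    mid <- sz[-which_ax][1] / 2
    oth <- if (axis == "x") 2 else 1
    pa <- which.min((m$nodes[, which_ax] - 10)^2 + (m$nodes[, oth] - mid)^2)
    pb <- which.min((m$nodes[, which_ax] - 25)^2 + (m$nodes[, oth] - mid)^2)
    (m$nodes[pb, which_ax] - m$nodes[pa, which_ax]) / (lat[pb] - lat[pa])
  }
  cvl <- run_cv(c(30, 10), "x")
  cvt <- run_cv(c(10, 30), "y")
  expect_gt(cvl, cvt)
  target <- sqrt(0.22 / 0.055)
  expect_lt(abs(cvl / cvt - target) / target, 0.15)
})

test_that("lesions are idempotent and a full-width line blocks conduction", {
  m <- sheet_mesh(c(20, 8), 1)
  cond <- conductivity_field(m)
  cent <- (m$nodes[m$triangles[, 1], ] + m$nodes[m$triangles[, 2], ] +
             m$nodes[m$triangles[, 3], ]) / 3
  line_el <- which(abs(cent[, 1] - 10) < 1)
  c1 <- apply_lesion(cond, line_el)
  c2 <- apply_lesion(c1, line_el)
  expect_identical(c1, c2)
  expect_true(all(c1$sigma_l[line_el] == 0.001))
  expect_warning(apply_lesion(cond, integer(0)), "empty")
  sys <- monodomain_system(m, c1)
  rec <- simulate_tissue(sys, init_tissue_state(sys), 0, 80,
                         list(stimulus(1, which(m$nodes[, 1] < 1))),
                         dt_ms = 0.05)
  lat <- activation_times(rec)$lat
  distal <- m$nodes[, 1] > 12
  expect_true(all(is.na(lat[distal])))
  proximal <- m$nodes[, 1] < 8
  expect_true(all(!is.na(lat[proximal])))
})

test_that("activation times recover an analytic traveling wave", {
  m <- sheet_20()
  v <- 0.5  # mm/ms
  times <- seq(0, 60, by = 1)
  frames <- matrix(-80, nrow(m$nodes), length(times))
  for (k in seq_along(times))
    frames[, k] <- ifelse(m$nodes[, 1] / v <= times[k], 20, -80)
  rec <- structure(list(times = times, frames = frames, record_dt = 1,
                        stim_times = numeric(0), ok = TRUE),
                   class = "tissue_recording")
  lat <- activation_times(rec)$lat
  inner <- m$nodes[, 1] > 2 & m$nodes[, 1] < 18
  fit <- lm(lat[inner] ~ m$nodes[inner, 1])
  expect_lt(abs(coef(fit)[2] - 1 / v) / (1 / v), 0.02)
  # constant subthreshold trace stays unactivated
  rec$frames[] <- -80
  expect_true(all(is.na(activation_times(rec)$lat)))
})

test_that("layer coupling spans independent to monolayer behavior", {
  mk <- function() {
    m <- sheet_mesh(c(12, 5), 1)
    monodomain_system(m)
  }
  sa <- mk(); sb <- mk()
  n <- nrow(sa$mesh$nodes)
  st2 <- rbind(init_tissue_state(sa), init_tissue_state(sb))
  stim_a <- stimulus(1, which(sa$mesh$nodes[, 1] < 1))
  # zero coupling: layer b never activates
  c0 <- couple_layers(sa, sb, 0)
  r0 <- simulate_tissue(c0, st2, 0, 50, list(stim_a), dt_ms = 0.02)
  expect_true(all(r0$frames[(n + 1):(2 * n), ] < -60))
  expect_true(any(r0$frames[1:n, ] > 0))
  # strong coupling: both layers activate nearly identically
  cs <- couple_layers(sa, sb, 10)
  rs <- simulate_tissue(cs, st2, 0, 50, list(stim_a), dt_ms = 0.02)
  expect_true(any(rs$frames[(n + 1):(2 * n), ] > 0))
  act <- rs$frames[1:n, 30] > -60
  expect_lt(max(abs(rs$frames[cbind(which(act), 30)] -
                    rs$frames[cbind(which(act) + n, 30)])), 1)
  # identical layers with identical stimuli produce identical solutions
  stim_b <- stimulus(1, which(sb$mesh$nodes[, 1] < 1) + n)
  ri <- simulate_tissue(c0, st2, 0, 30, list(stim_a, stim_b), dt_ms = 0.02)
  expect_equal(ri$frames[1:n, ], ri$frames[(n + 1):(2 * n), ],
               tolerance = 1e-12)
  expect_error(couple_layers(sa, monodomain_system(sheet_mesh(c(8, 5), 1)),
                             1), "matching")
})

test_that("simulation is deterministic for fixed inputs", {
  m <- sheet_mesh(c(8, 8), 1)
  sys <- monodomain_system(m)
  st <- init_tissue_state(sys)
  stim <- list(stimulus(1, which(m$nodes[, 1] < 1)))
  r1 <- simulate_tissue(sys, st, 0, 25, stim, dt_ms = 0.02)
  r2 <- simulate_tissue(sys, st, 0, 25, stim, dt_ms = 0.02)
  expect_identical(r1$frames, r2$frames)
})

test_that("time-step refinement changes the solution by < 0.5 mV RMS", {
  m <- sheet_mesh(c(10, 5), 1)
  sys <- monodomain_system(m)
  st <- init_tissue_state(sys)
  stim <- list(stimulus(0, which(m$nodes[, 1] < 1)))
  r1 <- simulate_tissue(sys, st, 0, 5, stim, dt_ms = 0.01, record_dt = 5)
  r2 <- simulate_tissue(sys, st, 0, 5, stim, dt_ms = 0.005, record_dt = 5)
  v1 <- r1$frames[, ncol(r1$frames)]
  v2 <- r2$frames[, ncol(r2$frames)]
  expect_lt(sqrt(mean((v1 - v2)^2)), 0.5)
})
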
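unwrap_test <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}
wrapv <- function(x) (x + pi) %% (2 * pi) - pi

test_that("Hilbert phase advances linearly for a sinusoid", {
  times <- seq(0, 1000, by = 1)
  omega <- 2 * pi / 150  # rad/ms
  frames <- rbind(30 * sin(omega * times) - 40,
                  rep(-80, length(times)))  # node 2 constant: masked
  rec <- structure(list(times = times, frames = frames, record_dt = 1,
                        stim_times = numeric(0), ok = TRUE),
                   class = "tissue_recording")
  mv <- compute_phase(rec)
  expect_true(mv$mask[1])
  expect_false(mv$mask[2])
  expect_true(all(is.na(mv$phase[2, ])))
  inner <- 100:900
  slope <- diff(unwrap_test(mv$phase[1, inner])) / diff(times[inner])[1]
  expect_lt(abs(mean(slope) - omega) / omega, 0.01)
})

test_that("a paced action-potential train advances 2*pi per beat", {
  p <- make_region_params("LA_body")
  r <- pace_single_cell(p, 400, 6, dt_ms = 0.02, record_dt = 1)
  rec <- structure(list(times = r$t, frames = matrix(r$Vm, 1),
                        record_dt = 1, stim_times = numeric(0), ok = TRUE),
                   class = "tissue_recording")
  mv <- compute_phase(rec, t_start = 200, t_end = 2200)  # 5 beats
  un <- unwrap_test(mv$phase[1, ])
  total <- un[length(un)] - un[1]
  expect_lt(abs(abs(total) - 5 * 2 * pi), 2.5)  # within ~0.4 cycle
})

test_that("topological charge detects analytic vortices exactly", {
  m <- sheet_64()
  cent <- (m$nodes[m$triangles[, 1], ] + m$nodes[m$triangles[, 2], ] +
             m$nodes[m$triangles[, 3], ]) / 3
  # single positive vortex
  ctr <- matrix(c(31.4, 33.2), 1)
  ph <- vortex_phase(m$nodes[, 1:2, drop = FALSE], ctr, +1)
  det <- detect_ps(ph, m)
  expect_equal(nrow(det), 1)
  expect_equal(det$chirality, 1)
  # the detected element contains the vortex centre
  expect_lt(sqrt((det$x - ctr[1])^2 + (det$y - ctr[2])^2),
            2 * mean(m$edge_length))
  # planar phase ramp: no singularities
  ramp <- wrapv(0.3 * m$nodes[, 1])
  expect_equal(nrow(detect_ps(ramp, m)), 0)
  # two opposite vortices: two PSs, net charge zero
  ctr2 <- rbind(c(20.2, 20.7), c(44.6, 41.3))
  ph2 <- vortex_phase(m$nodes[, 1:2, drop = FALSE], ctr2, c(+1, -1))
  det2 <- detect_ps(ph2, m)
  expect_equal(nrow(det2), 2)
  expect_equal(sum(det2$chirality), 0)
})

test_that("detector agrees with brute-force winding on 100 random fields", {
  m <- sheet_64()
  cent <- (m$nodes[m$triangles[, 1], ] + m$nodes[m$triangles[, 2], ] +
             m$nodes[m$triangles[, 3], ]) / 3
  set.seed(101)
  n_ok <- 0
  for (rep in 1:100) {
    k <- sample(1:3, 1)
    ctr <- random_vortices(k, 8, 56)
    chi <- sample(c(-1, 1), k, replace = TRUE)
    ph <- vortex_phase(m$nodes[, 1:2, drop = FALSE], ctr, chi)
    det <- detect_ps(ph, m)
    # ground truth: count and net charge
    count_ok <- nrow(det) == k && sum(det$chirality) == sum(chi)
    # per vortex: a detection of the right chirality lies within one
    # element of the centre, and brute-force winding of the analytic field
    # around the element containing the centre reproduces that chirality
    wind_ok <- all(vapply(seq_len(k), function(v) {
      dd <- sqrt((det$x - ctr[v, 1])^2 + (det$y - ctr[v, 2])^2)
      r <- which.min(dd)
      host <- which.min((cent[, 1] - ctr[v, 1])^2 +
                          (cent[, 2] - ctr[v, 2])^2)
      tri <- m$triangles[host, ]
      dd[r] < 2 * mean(m$edge_length) && det$chirality[r] == chi[v] &&
        brute_winding(m$nodes[tri, 1:2, drop = FALSE], ctr, chi) == chi[v]
    }, logical(1)))
    if (count_ok && wind_ok) n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 100)
})

test_that("net topological charge is conserved frame to frame", {
  m <- sheet_64()
  set.seed(7)
  for (frame in 1:20) {
    k <- sample(1:3, 1)
    ctr <- cbind(runif(k, 10, 54), runif(k, 10, 54))
    chi <- sample(c(-1, 1), k, replace = TRUE)
    # paired fields: add mirrored vortices so analytic net charge is zero
    ctr_all <- rbind(ctr, ctr + matrix(c(6, 5), k, 2, byrow = TRUE))
    chi_all <- c(chi, -chi)
    ph <- vortex_phase(m$nodes[, 1:2, drop = FALSE], ctr_all, chi_all)
    det <- detect_ps(ph, m)
    expect_equal(sum(det$chirality), 0)
  }
})

test_that("tracking links, splits and recovers meandering vortices", {
  m <- sheet_64()
  cent <- (m$nodes[m$triangles[, 1], ] + m$nodes[m$triangles[, 2], ] +
             m$nodes[m$triangles[, 3], ]) / 3
  # stationary detection over 10 frames -> one trajectory, duration 9
  el <- which.min((cent[, 1] - 30)^2 + (cent[, 2] - 30)^2)
  det1 <- lapply(1:10, function(k)
    data.frame(element = el, chirality = 1,
               x = cent[el, 1], y = cent[el, 2], z = 0))
  tr1 <- track_ps(det1, times = 0:9)
  expect_equal(nrow(trajectory_summary(tr1)), 1)
  expect_equal(trajectory_summary(tr1)$duration, 9)
  # a jump beyond the threshold starts a new trajectory
  el2 <- which.min((cent[, 1] - 50)^2 + (cent[, 2] - 50)^2)
  det2 <- det1
  det2[[6]] <- data.frame(element = el2, chirality = 1,
                          x = cent[el2, 1], y = cent[el2, 2], z = 0)
  det2[[7]] <- det2[[6]]; det2[[8]] <- det2[[6]]
  det2[[9]] <- det2[[6]]; det2[[10]] <- det2[[6]]
  tr2 <- track_ps(det2, times = 0:9, max_jump_mm = 5)
  expect_equal(nrow(trajectory_summary(tr2)), 2)
  # meandering vortex on a circle of radius 6, 2 mm per frame: recovered
  # within one element diameter
  angs <- seq(0, 2 * pi, length.out = 25)
  truth <- cbind(32 + 6 * cos(angs), 32 + 6 * sin(angs))
  dets <- lapply(seq_along(angs), function(k) {
    ph <- vortex_phase(m$nodes[, 1:2, drop = FALSE],
                       truth[k, , drop = FALSE], +1, offset = 0.3 * k)
    detect_ps(ph, m)
  })
  tr3 <- track_ps(dets, times = seq_along(angs), max_jump_mm = 5)
  expect_equal(nrow(trajectory_summary(tr3)), 1)
  d3 <- as.data.frame(tr3)
  err <- sqrt((d3$x - truth[, 1])^2 + (d3$y - truth[, 2])^2)
  expect_lt(max(err), 2 * mean(m$edge_length))
})

test_that("density maps normalize, decay and are scale invariant", {
  m <- sheet_64()
  cent <- (m$nodes[m$triangles[, 1], ] + m$nodes[m$triangles[, 2], ] +
             m$nodes[m$triangles[, 3], ]) / 3
  el <- which.min((cent[, 1] - 30)^2 + (cent[, 2] - 30)^2)
  traj <- data.frame(id = 1, t = 1:20, element = el, chirality = 1,
                     x = cent[el, 1], y = cent[el, 2], z = 0)
  dm <- density_map(traj, m, radius_mm = 5)
  expect_equal(max(dm$density), 1)
  expect_equal(which.max(dm$density), el)
  # monotone decay with distance from the source (on average)
  d <- sqrt((cent[, 1] - cent[el, 1])^2 + (cent[, 2] - cent[el, 2])^2)
  near <- dm$density[d > 1 & d < 2]
  far <- dm$density[d > 3 & d < 4]
  expect_gt(min(near), max(far))
  # two equally occupied sites both reach ~1
  el2 <- which.min((cent[, 1] - 45)^2 + (cent[, 2] - 45)^2)
  traj2 <- rbind(traj, transform(traj, id = 2, element = el2,
                                 x = cent[el2, 1], y = cent[el2, 2]))
  dm2 <- density_map(traj2, m, radius_mm = 5)
  expect_gt(min(dm2$density[c(el, el2)]), 0.99)
  # doubling all counts leaves the normalized map unchanged
  traj_dbl <- rbind(traj, traj)
  expect_equal(density_map(traj_dbl, m, radius_mm = 5)$density,
               dm$density, tolerance = 1e-12)
  # empty input: all-zero map
  expect_true(all(density_map(traj[0, ], m)$density == 0))
})

test_that("rotor classification applies the 120 ms duration threshold", {
  s <- data.frame(id = 1:3, birth = c(0, 0, 0), death = c(119, 121, 300),
                  chirality = 1, duration = c(119, 121, 300))
  tr <- structure(data.frame(id = integer(0)), summary = s,
                  class = c("ps_trajectories", "data.frame"))
  expect_equal(classify_rotors(tr), c(2L, 3L))
  empty <- structure(data.frame(id = integer(0)),
                     summary = s[0, ],
                     class = c("ps_trajectories", "data.frame"))
  expect_length(classify_rotors(empty), 0)
})

test_that("regional statistics aggregate per subdivision", {
  m <- la_mesh_coarse()
  cent <- (m$nodes[m$triangles[, 1], ] + m$nodes[m$triangles[, 2], ] +
             m$nodes[m$triangles[, 3], ]) / 3
  el3 <- which(m$subdivision == 3)[10]
  traj <- data.frame(id = 1, t = 0:99, element = el3, chirality = 1,
                     x = cent[el3, 1], y = cent[el3, 2], z = 0)
  class(traj) <- c("ps_trajectories", "data.frame")
  attr(traj, "summary") <- data.frame(id = 1, birth = 0, death = 99,
                                      chirality = 1, duration = 99)
  # periodic activation at CL 185 everywhere
  acts <- replicate(nrow(m$nodes), seq(10, 1000, by = 185),
                    simplify = FALSE)
  rec <- pulse_recording(acts, t_end = 1000)
  st <- regional_stats(traj, rotor_ids = integer(0), rec, m)
  expect_equal(st$ps_mean[3], 1)
  expect_true(all(st$ps_mean[-3] == 0))
  expect_true(all(abs(st$cl_mean_ms - 185) < 1))
  expect_equal(max(st$ps_density), 1)
})
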
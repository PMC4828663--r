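test_that("edge selection weight follows the 4:1 fiber-alignment rule", {
  expect_equal(edge_selection_weight(0), 4)
  expect_equal(edge_selection_weight(pi / 2), 1)
  expect_equal(edge_selection_weight(pi / 4), 2.5)
  expect_error(edge_selection_weight(-0.2), "0, pi/2")
  expect_error(edge_selection_weight(2), "0, pi/2")
})

test_that("edge selection replays an independent scalar RNG loop", {
  m <- sheet_20()
  lge <- rep(0.5, nrow(m$triangles))
  alpha <- 0.3
  fm <- select_fibrotic_edges(m, lge, alpha, seed = 42)
  # oracle: scalar loop over edges with the same RNG stream and the
  # selection rule written out longhand
  w <- numeric(nrow(m$edges))
  for (e in seq_len(nrow(m$edges))) {
    t1 <- m$edge_tri[e, 1]; t2 <- m$edge_tri[e, 2]
    f1 <- m$fiber[t1, ]
    f2 <- if (is.na(t2)) f1 else m$fiber[t2, ]
    if (sum(f1 * f2) < 0) f2 <- -f2
    fa <- (f1 + f2); fa <- fa / sqrt(sum(fa^2))
    ev <- m$nodes[m$edges[e, 2], ] - m$nodes[m$edges[e, 1], ]
    ev <- ev / sqrt(sum(ev^2))
    th <- acos(min(1, abs(sum(fa * ev))))
    L1 <- lge[t1]; L2 <- if (is.na(t2)) L1 else lge[t2]
    w[e] <- alpha * (4 * cos(th)^2 + sin(th)^2) * (L1 + L2) / 2
  }
  set.seed(42)
  u <- runif(nrow(m$edges))
  expect_identical(fm$selected, w > u)
  expect_equal(sum(fm$selected), sum(w > u))
})

test_that("degenerate likelihoods behave as expected", {
  m <- sheet_20()
  none <- select_fibrotic_edges(m, rep(0, nrow(m$triangles)), 5, seed = 1)
  expect_equal(sum(none$selected), 0)
  expect_equal(length(none$components), 0)
  all_sel <- select_fibrotic_edges(m, rep(1, nrow(m$triangles)), 1.01,
                                   seed = 1)
  expect_true(all(all_sel$selected))  # alpha * w * L >= 1.01 > u everywhere
  expect_equal(length(all_sel$removed_elements), nrow(m$triangles))
  expect_error(select_fibrotic_edges(m, rep(1, nrow(m$triangles)), -1),
               "positive")
})

test_that("parallel edges are selected 4x more often than perpendicular", {
  m <- sheet_20()  # fibers along +x
  ev <- m$nodes[m$edges[, 2], 1:2] - m$nodes[m$edges[, 1], 1:2]
  horiz <- abs(ev[, 2]) < 1e-9
  vert <- abs(ev[, 1]) < 1e-9
  lge <- rep(1, nrow(m$triangles))
  alpha <- 0.05  # parallel probability 0.2, perpendicular 0.05
  nsel_h <- 0; nh <- 0; nsel_v <- 0; nv <- 0
  for (s in 1:40) {
    fm <- select_fibrotic_edges(m, lge, alpha, seed = s)
    nsel_h <- nsel_h + sum(fm$selected[horiz]); nh <- nh + sum(horiz)
    nsel_v <- nsel_v + sum(fm$selected[vert]); nv <- nv + sum(vert)
  }
  expect_gt(nh, 1e4)  # >= 10^4 seeded draws per class
  expect_gt(nv, 1e4)
  ratio <- (nsel_h / nh) / (nsel_v / nv)
  expect_lt(abs(ratio - 4) / 4, 0.05)
})

test_that("selected fraction grows with alpha and with likelihood", {
  m <- sheet_20()
  lge <- rep(0.5, nrow(m$triangles))
  fr <- vapply(c(0.05, 0.1, 0.2, 0.4), function(a)
    mean(select_fibrotic_edges(m, lge, a, seed = 3)$selected), numeric(1))
  expect_true(all(diff(fr) > 0))
  fr_l <- vapply(c(0.2, 0.5, 1), function(l)
    mean(select_fibrotic_edges(m, rep(l, nrow(m$triangles)), 0.2,
                               seed = 3)$selected), numeric(1))
  expect_true(all(diff(fr_l) > 0))
})

test_that("alpha calibration reaches an attainable target monotonically", {
  m <- sheet_20()
  lge <- rep(0.6, nrow(m$triangles))
  target <- 1500  # a couple of coarse edges, below the percolation jump
  cal <- calibrate_alpha(m, lge, target_median_um = target, n_seeds = 6,
                         seed = 2, tol_um = 700)
  expect_true(cal$converged)
  expect_lt(abs(cal$achieved_median_um - target), 700)
  # direct sweep oracle: the objective is non-decreasing in alpha
  meds <- vapply(cal$alpha * c(0.25, 1, 4), function(a) {
    mean(vapply(1:6, function(s) {
      fm <- select_fibrotic_edges(m, lge, a, seed = s + 1)
      mm <- median_cluster_length(fm)
      if (is.na(mm)) 0 else mm
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meds) >= 0))
  expect_error(calibrate_alpha(m, rep(0, nrow(m$triangles))), "zero")
})

test_that("edge splitting decouples cracks while conserving geometry", {
  m <- sheet_20()
  no_sel <- atrialab:::fibrosis_map_from_selection(
    m, rep(FALSE, nrow(m$edges)), 1, 1)
  expect_identical(split_edges(m, no_sel), m)

  # single interior split edge: +2 nodes, triangle count unchanged
  interior <- which(!is.na(m$edge_tri[, 2]))
  cent_e <- (m$nodes[m$edges[, 1], 1:2] + m$nodes[m$edges[, 2], 1:2]) / 2
  mid <- interior[which.min((cent_e[interior, 1] - 10)^2 +
                            (cent_e[interior, 2] - 10)^2)]
  sel <- rep(FALSE, nrow(m$edges)); sel[mid] <- TRUE
  fm1 <- atrialab:::fibrosis_map_from_selection(m, sel, 1, 1)
  ms <- split_edges(m, fm1)
  expect_equal(nrow(ms$nodes), nrow(m$nodes) + 2)
  expect_equal(nrow(ms$triangles), nrow(m$triangles))
  expect_equal(sum(triangle_areas(ms)), sum(triangle_areas(m)),
               tolerance = 1e-12)
  # the two triangles at the split edge no longer share it: every edge
  # instance at that location is now a slit (boundary) edge
  pa <- m$nodes[m$edges[mid, 1], ]; pb <- m$nodes[m$edges[mid, 2], ]
  same_pt <- function(q, p) sqrt(rowSums(sweep(q, 2, p)^2)) < 1e-9
  at_a <- which(same_pt(ms$nodes, pa)); at_b <- which(same_pt(ms$nodes, pb))
  inst <- which(ms$edges[, 1] %in% c(at_a, at_b) &
                ms$edges[, 2] %in% c(at_a, at_b))
  expect_equal(length(inst), 2)
  expect_true(all(is.na(ms$edge_tri[inst, 2])))
})

test_that("splitting a dense map preserves electrical connectivity", {
  m <- la_mesh_coarse()
  lge <- build_lge_map(m, seed = 3)
  fm <- select_fibrotic_edges(m, lge, alpha = 0.6, seed = 8)
  ms <- suppressMessages(split_edges(m, fm))
  expect_silent(validate_mesh(ms, check_euler = FALSE))
  keep <- setdiff(seq_len(nrow(m$triangles)), fm$removed_elements)
  before <- atrialab:::tri_components(m$triangles[keep, , drop = FALSE])
  after <- atrialab:::tri_components(ms$triangles)
  expect_equal(after, before)
  expect_gt(nrow(ms$nodes), nrow(m$nodes))
})

test_that("a split line delays conduction around it", {
  # 20 x 12 mm sheet at 1 mm; a 10 mm vertical split line in the middle.
  # A plane wave from the left must detour, arriving later directly behind
  # the line than at the same x beside it.
  m <- sheet_mesh(c(20, 12), 1)
  cent_e <- (m$nodes[m$edges[, 1], ] + m$nodes[m$edges[, 2], ]) / 2
  ev <- m$nodes[m$edges[, 2], ] - m$nodes[m$edges[, 1], ]
  # the grid column of vertical edges nearest x = 10
  xs <- sort(unique(m$nodes[, 1]))
  xcol <- xs[which.min(abs(xs - 10))]
  on_line <- abs(cent_e[, 1] - xcol) < 0.05 & cent_e[, 2] > 0.5 &
    cent_e[, 2] < 10.5 & abs(ev[, 1]) < 1e-9
  sel <- on_line
  fm <- atrialab:::fibrosis_map_from_selection(m, sel, 1, 1)
  ms <- suppressMessages(split_edges(m, fm))
  run <- function(mesh) {
    sys <- monodomain_system(mesh)
    rec <- simulate_tissue(sys, init_tissue_state(sys), 0, 140,
                           list(stimulus(1, which(mesh$nodes[, 1] < 1))),
                           dt_ms = 0.05)
    activation_times(rec)$lat
  }
  lat_ref <- run(m)
  lat_split <- run(ms)
  behind_ref <- which(abs(m$nodes[, 1] - (xcol + 1)) < 0.5 &
                      abs(m$nodes[, 2] - 5) < 0.6)[1]
  behind_spl <- which(abs(ms$nodes[, 1] - (xcol + 1)) < 0.5 &
                      abs(ms$nodes[, 2] - 5) < 0.6)[1]
  expect_gt(lat_split[behind_spl] - lat_ref[behind_ref], 2)
})
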
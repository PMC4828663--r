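test_that("pearson matches a brute-force covariance computation", {
  set.seed(5)
  for (rep in 1:50) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    p <- pearson(x, y)
    # two-pass covariance oracle
    r_bf <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    tstat <- r_bf * sqrt((n - 2) / (1 - r_bf^2))
    p_bf <- 2 * pt(-abs(tstat), df = n - 2)
    expect_lt(abs(p$r - r_bf), 1e-12)
    expect_lt(abs(p$p - p_bf), 1e-12)
  }
  x <- 1:8
  self <- pearson(x, x)
  expect_equal(self$r, 1)
  expect_lt(self$p, 1e-12)
  flat <- pearson(x, rep(2, 8))
  expect_false(flat$defined)
  expect_true(is.na(flat$r))
  expect_error(pearson(1:3, 1:4), "equal length")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("density normalization follows the 0-1 convention", {
  expect_equal(normalize_densities(c(2, 1, 4)), c(0.5, 0.25, 1))
  v <- c(0.3, 1, 0.7)
  expect_equal(normalize_densities(v), v)
  expect_equal(normalize_densities(c(0, 1, 1, 0)), c(0, 1, 1, 0))  # binary
  expect_equal(normalize_densities(rep(0, 4)), rep(0, 4))
  expect_equal(normalize_densities(5), 1)
})

test_that("outcome classification separates sinus, AT and pAF", {
  n <- 6
  # quiescent tail -> sinus
  quiet <- pulse_recording(replicate(n, c(50), simplify = FALSE),
                           t_end = 2000)
  out_s <- classify_outcome(quiet, trajectories = data.frame(
    id = integer(0), t = numeric(0), element = integer(0)),
    rotor_ids = integer(0), quiet_tail_s = 1)
  expect_equal(out_s$classification, "sinus")
  expect_equal(out_s$success, 1L)
  # regular activity with one persistent rotor -> AT
  acts <- replicate(n, seq(50, 1950, by = 200), simplify = FALSE)
  busy <- pulse_recording(acts, t_end = 2000)
  traj_at <- data.frame(id = 1, t = 500:2000, element = 1, chirality = 1,
                        x = 0, y = 0, z = 0)
  out_at <- classify_outcome(busy, traj_at, rotor_ids = 1L,
                             quiet_tail_s = 0.5)
  expect_equal(out_at$classification, "AT")
  expect_equal(out_at$success, 1L)
  # irregular activity with two concurrent rotors -> pAF
  acts_irr <- lapply(1:n, function(i) {
    set.seed(i); cumsum(c(50, 120 + runif(12, 0, 120)))
  })
  fib <- pulse_recording(acts_irr, t_end = 2000)
  traj_af <- rbind(
    data.frame(id = 1, t = 500:2000, element = 1, chirality = 1,
               x = 0, y = 0, z = 0),
    data.frame(id = 2, t = 500:2000, element = 2, chirality = -1,
               x = 5, y = 5, z = 0))
  out_af <- classify_outcome(fib, traj_af, rotor_ids = c(1L, 2L),
                             quiet_tail_s = 0.5)
  expect_equal(out_af$classification, "pAF")
  expect_equal(out_af$success, 0L)
  expect_error(classify_outcome(quiet, traj_at, 1L, quiet_tail_s = 10),
               "shorter")
})

test_that("outcome labels are stable across recording frame rates", {
  n <- 6
  acts <- replicate(n, seq(50, 1950, by = 200), simplify = FALSE)
  traj <- data.frame(id = 1, t = 500:2000, element = 1, chirality = 1,
                     x = 0, y = 0, z = 0)
  for (dt in c(0.5, 1, 2)) {
    rec <- pulse_recording(acts, t_end = 2000, record_dt = dt)
    out <- classify_outcome(rec, traj, rotor_ids = 1L, quiet_tail_s = 0.5)
    expect_equal(out$classification, "AT")
  }
})

test_that("correlation tables mirror the regional analysis layout", {
  ps <- la_reference_densities$ps_rspv
  fib <- la_reference_densities$fibrosis
  outcomes <- expand.grid(shape = c("circle", "line"),
                          size_cm = c(0.5, 1.5), subdivision = 1:8)
  # all-failure row for circle 0.5; thresholded-density outcomes for line
  outcomes$success <- 0L
  thr <- as.integer(ps > 0.3)
  line_rows <- outcomes$shape == "line" & outcomes$size_cm == 1.5
  outcomes$success[line_rows] <- thr[outcomes$subdivision[line_rows]]
  tab <- correlation_table(outcomes, ps_density = ps, fib_density = fib)
  row_fail <- tab[tab$shape == "circle" & tab$size_cm == 0.5, ]
  expect_equal(row_fail$r_ps_disp, "-")
  expect_equal(row_fail$p_fib_disp, "-")
  # outcome equal to a binary density vector correlates perfectly with it
  tab2 <- correlation_table(outcomes[line_rows, ],
                            ps_density = thr, fib_density = fib)
  expect_equal(tab2$r_ps, 1)
  # consistent permutation of subdivisions leaves r unchanged
  perm <- c(3, 1, 4, 2, 8, 5, 7, 6)
  oc2 <- outcomes[line_rows, ]
  oc2$subdivision <- match(oc2$subdivision, perm)
  tab3 <- correlation_table(oc2, ps_density = ps[perm],
                            fib_density = fib[perm])
  tab_ref <- correlation_table(outcomes[line_rows, ], ps, fib)
  expect_equal(tab3$r_ps, tab_ref$r_ps, tolerance = 1e-12)
  expect_equal(tab3$r_fib, tab_ref$r_fib, tolerance = 1e-12)
})
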
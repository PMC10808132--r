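test_that("series stiffness follows the reciprocal sum rule", {
  expect_equal(effective_stiffness(c(11.42, 11.42)), 5.71)
  expect_equal(effective_stiffness(c(6, 3)), 2)
  expect_equal(effective_stiffness(7.3), 7.3)
  # properties: below the softest spring, permutation invariant, halves for twins
  set.seed(1)
  for (i in 1:20) {
    ks <- runif(sample(2:5, 1), 0.1, 50)
    expect_lt(effective_stiffness(ks), min(ks) + 1e-12)
    expect_equal(effective_stiffness(ks), effective_stiffness(rev(ks)))
  }
  k <- runif(1, 1, 10)
  expect_equal(effective_stiffness(c(k, k)), k / 2)
  expect_error(effective_stiffness(c(1, -2)), "positive")
})

test_that("loading-rate conversion reproduces the published protocol rate", {
  expect_equal(loading_rate_si(5e-8), 1.4e4, tolerance = 0.005)
  expect_equal(loading_rate_si(0), 0)
  expect_equal(loading_rate_si(1), 0.8518 / 3.03e-12)
  expect_error(loading_rate_si(-1), "non-negative")
})

test_that("exponential moving average follows the standard recursion", {
  expect_equal(ema(c(0, 1, 1), 0.5), c(0, 0.5, 0.75))
  x <- rnorm(50)
  expect_equal(ema(x, 1), x)
  expect_equal(ema(rep(3.2, 10), 0.3), rep(3.2, 10))
  # bounded by the running extrema of the input
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(100)
    y <- ema(x, runif(1, 0.05, 0.95))
    expect_true(all(y <= cummax(x) + 1e-12))
    expect_true(all(y >= cummin(x) - 1e-12))
  }
  expect_error(ema(x, 0), "alpha")
  expect_error(ema(x, 1.5), "alpha")
  expect_error(ema(numeric(0), 0.5), "non-empty")
})

test_that("trap force is k_eff times the summed projected spring stretches", {
  # two static beads; the moving trap translates 2 nm along x
  pos <- array(0, c(2, 3, 5))
  pos[2, 1, ] <- 4   # bead b at x = 4 nm in every frame
  times_s <- seq(0, 2e-4, length.out = 5)
  traj <- make_trajectory(pos, times_s = times_s)
  pr <- trap_protocol(0L, 1L, 11.42, 11.42, anchor_a = c(0, 0, 0),
                      start_b = c(4, 0, 0), rate = 1e4, axis = c(1, 0, 0))
  cv <- force_extension_curve(traj, pr)
  expect_equal(attr(cv, "k_eff"), 5.71)
  expect_equal(cv$force_raw[1], 0)
  expect_equal(cv$force_raw[5], 5.71 * 2)  # 11.42 pN after 2 nm translation
  # nucleotide-separation extension is zero for static beads
  expect_equal(cv$extension, rep(0, 5))
  # beads tracking their traps exactly give identically zero force
  pos2 <- pos
  pos2[2, 1, ] <- (4 + times_s * 1e4) / 1  # bead follows the moving trap
  cv2 <- force_extension_curve(make_trajectory(pos2, times_s = times_s), pr)
  expect_equal(cv2$force_raw, rep(0, 5), tolerance = 1e-9)
})

test_that("reconstructed force is invariant under rigid translation", {
  run <- run_small(seed = 3, n_steps = 2e4, stride = 200)
  shift <- c(5.3, -2.1, 8.9) # nm
  traj2 <- run$trajectory
  for (d in 1:3)
    traj2$positions[, d, ] <- traj2$positions[, d, ] +
      shift[d] / oxdna_units()$nm_per_length_unit
  pr <- run$protocol
  pr2 <- trap_protocol(pr$index_a, pr$index_b, pr$k_a, pr$k_b,
                       pr$anchor_a + shift, pr$start_b + shift, pr$rate, pr$axis)
  cv2 <- force_extension_curve(traj2, pr2)
  expect_equal(cv2$force_raw, run$curve$force_raw, tolerance = 1e-8)
})

test_that("quasi-static pull of a Hookean dumbbell shows the three-spring series slope", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0))
  k_s <- 10
  p <- sim_params(seed = 1, temperature = 0, dt = 1e-9, n_steps = 2e5, stride = 500)
  pr <- trap_protocol(0L, 1L, 11.42, 11.42, c(0, 0, 0), c(1, 0, 0),
                      rate = 1e4, axis = c(1, 0, 0))
  res <- simulate_beads(pos, cbind(0L, 1L), 1, k_s,
                        matrix(integer(0), 0, 2), numeric(0), numeric(0),
                        numeric(0), p, pr)
  traj <- make_trajectory(res$frames, times_s = res$times)
  cv <- force_extension_curve(traj, pr, convention = "trap")
  settled <- cv[cv$extension > max(cv$extension) / 2, ]
  slope <- unname(coef(lm(force_raw ~ extension, settled))[2])
  expect_equal(slope, effective_stiffness(c(11.42, 11.42, k_s)), tolerance = 0.05)
})

test_that("rupture detection marks a peak followed by a force drop", {
  # ramp to 50 pN with a sharp post-peak drop (a slow symmetric descent would
  # not halve the force inside the default 10% inspection window)
  ramp <- data.frame(time = 1:101, extension = 1:101,
                     force_ema = c(seq(0, 50, length.out = 91),
                                   seq(45, 0, length.out = 10)))
  rup <- detect_rupture(ramp)
  expect_true(rup$valid)
  expect_equal(rup$rupture_force, 50)
  expect_equal(rup$rupture_frame, 91)

  mono <- data.frame(time = 1:100, force_ema = seq(1, 60, length.out = 100))
  rup2 <- detect_rupture(mono)
  expect_false(rup2$valid)
  expect_true(is.na(rup2$rupture_force))
})

test_that("detected rupture frame matches the simulator bond-state oracle", {
  for (seed in c(2, 7)) {
    run <- run_small(fb_bp = 3L, seed = seed)
    rup <- detect_rupture(run$curve)
    expect_true(rup$valid)
    oracle <- last_intact_frame(run)
    nf <- n_frames(run$trajectory)
    expect_lt(abs(rup$rupture_frame - oracle), 0.05 * nf)
  }
})
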
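test_that("geometric hydrogen-bond criterion matches a brute-force oracle", {
  m <- small_model()
  f0 <- m$frame0
  # ideal built duplex geometry: every designed pair is bound
  bound <- detect_base_pairs(f0$positions[, , 1], f0$base_vectors[, , 1],
                             m$pairs, m$topology)
  expect_true(all(bound))
  # strands rigidly separated by 10 length units: nothing bound
  pos_apart <- f0$positions[, , 1]
  s5 <- which(m$topology$strand == 5L)
  pos_apart[s5, 1] <- pos_apart[s5, 1] + 10
  bound2 <- detect_base_pairs(pos_apart, f0$base_vectors[, , 1], m$pairs)
  expect_true(all(!bound2[m$fb_pairs]))

  # randomized configurations against an independent per-pair scan
  set.seed(11)
  n <- 30
  for (rep in 1:25) {
    pos <- matrix(rnorm(n * 3, sd = 0.8), n, 3)
    bv <- matrix(rnorm(n * 3), n, 3)
    bv <- bv / sqrt(rowSums(bv^2))
    pairs <- cbind(0:(n / 2 - 1), (n / 2):(n - 1))
    cutoff <- runif(1, 0.2, 1.5)
    got <- detect_base_pairs(pos, bv, pairs, distance_cutoff = cutoff)
    oracle <- vapply(seq_len(nrow(pairs)), function(k) {
      i <- pairs[k, 1] + 1; j <- pairs[k, 2] + 1
      si <- pos[i, ] + 0.4 * bv[i, ]; sj <- pos[j, ] + 0.4 * bv[j, ]
      sqrt(sum((si - sj)^2)) < cutoff && sum(bv[i, ] * bv[j, ]) < 0
    }, logical(1))
    expect_identical(got, oracle)
  }
})

test_that("reference pairs must be sequence complementary", {
  m <- small_model()
  f0 <- m$frame0
  bad <- m$pairs
  # pair a bead with a same-strand neighbor: generally non-complementary here
  bad[1, ] <- c(0L, 1L)
  expect_error(detect_base_pairs(f0$positions[, , 1], f0$base_vectors[, , 1],
                                 rbind(bad[1, ]), m$topology),
               "complementary")
})

test_that("denatured fraction counts unbound designed pairs", {
  # ten pairs of beads 0.68 nm apart, bases facing; 4 pairs tear off at the end
  n <- 20
  base <- matrix(0, n, 3)
  base[1:10, 2] <- 1; base[11:20, 2] <- -1
  pos <- array(0, c(n, 3, 3))
  for (f in 1:3) {
    pos[1:10, 1, f] <- seq(0, 18, by = 2)
    pos[11:20, 1, f] <- seq(0, 18, by = 2)
    pos[11:20, 2, f] <- 0.68
  }
  pos[11:14, 2, 3] <- 12  # last frame: pairs 1-4 separated
  traj <- make_trajectory(pos, base = base)
  pairs <- cbind(0:9, 10:19)
  frac <- denatured_fraction(traj, pairs)
  expect_equal(frac$fraction, c(0, 0, 0.4))
  expect_equal(attr(frac, "end_fraction"), 0.4)
  expect_true(all(frac$fraction >= 0 & frac$fraction <= 1))
  expect_error(denatured_fraction(traj, pairs[0, , drop = FALSE]), "empty")
})

test_that("pulling far past rupture denatures exactly the planted FB bonds", {
  run <- run_small(fb_bp = 3L, seed = 5, n_steps = 3e5)
  m <- run$model
  expect_gt(sum(run$events$fb), 0)
  fb_pairs <- m$pairs[m$fb_pairs, , drop = FALSE]
  frac <- denatured_fraction(run$trajectory, fb_pairs, distance_cutoff = 2.5)
  oracle <- mean(run$broken[m$fb_pairs])
  expect_equal(attr(frac, "end_fraction"), oracle, tolerance = 1e-9)
  # full-structure count: broken fraction matches the event-log oracle
  frac_all <- denatured_fraction(run$trajectory, m$pairs, distance_cutoff = 2.5)
  expect_equal(attr(frac_all, "end_fraction"), mean(run$broken),
               tolerance = 1 / length(run$broken) + 1e-9)
})

test_that("site distances convert positions to nm", {
  pos <- array(0, c(2, 3, 4))
  pos[2, , ] <- c(3, 4, 0) * 0.8518  # offset fixed in nm
  traj <- make_trajectory(pos)
  expect_equal(site_distance_series(traj, 0L, 0L), rep(0, 4))
  expect_equal(site_distance_series(traj, 0L, 1L), rep(5 * 0.8518, 4))
  expect_error(site_distance_series(traj, 0L, 5L), "out of range")
})

test_that("fluorophore-quencher separation jumps after rupture", {
  run <- run_small(fb_bp = 3L, seed = 5, n_steps = 3e5)
  d <- site_distance_series(run$trajectory, run$model$sites$fluorophore,
                            run$model$sites$quencher)
  lif <- last_intact_frame(run)
  pre <- d[1:lif]
  post <- d[(lif + 5):length(d)]
  expect_gt(max(post), mean(pre) + 3 * sd(pre))
})

test_that("incircle radius matches closed forms and a search oracle", {
  expect_equal(incircle_radius(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)), 1)
  a <- 6.8
  eq <- incircle_radius(c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0))
  expect_equal(eq, a / (2 * sqrt(3)))
  # collinear triangle is degenerate
  expect_equal(incircle_radius(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)), 0)

  # numerical maximum-inscribed-circle search in the triangle plane
  inscribed_oracle <- function(p1, p2, p3) {
    e1 <- p2 - p1; e2 <- p3 - p1
    u <- e1 / sqrt(sum(e1^2))
    w <- e2 - sum(e2 * u) * u; w <- w / sqrt(sum(w^2))
    v <- rbind(c(0, 0), c(sum(e1 * u), sum(e1 * w)), c(sum(e2 * u), sum(e2 * w)))
    edge_dist <- function(p, a, b) {
      t <- b - a; nrm <- c(-t[2], t[1]) / sqrt(sum(t^2))
      (p - a) %*% nrm
    }
    sgn <- sign(edge_dist(colMeans(v), v[1, ], v[2, ]))
    obj <- function(p) -min(sgn * edge_dist(p, v[1, ], v[2, ]),
                            sgn * edge_dist(p, v[2, ], v[3, ]),
                            sgn * edge_dist(p, v[3, ], v[1, ]))
    starts <- rbind(colMeans(v), (colMeans(v) + v[1, ]) / 2,
                    (colMeans(v) + v[2, ]) / 2, (colMeans(v) + v[3, ]) / 2)
    best <- Inf
    for (s in seq_len(nrow(starts))) {
      fit <- optim(starts[s, ], obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-14, maxit = 5000))
      fit <- optim(fit$par, obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-14, maxit = 5000))
      best <- min(best, fit$value)
    }
    -best
  }
  set.seed(21)
  for (i in 1:200) {
    tri <- matrix(rnorm(9, sd = 4), 3, 3)
    r <- incircle_radius(tri[1, ], tri[2, ], tri[3, ])
    if (r < 1e-3) next
    expect_equal(r, inscribed_oracle(tri[1, ], tri[2, ], tri[3, ]),
                 tolerance = 1e-3)
  }
})

test_that("incircle radius is rigid-motion invariant, scales linearly, and is below the circumradius", {
  set.seed(22)
  for (i in 1:50) {
    tri <- matrix(rnorm(9, sd = 3), 3, 3)
    r <- incircle_radius(tri[1, ], tri[2, ], tri[3, ])
    # random rotation (QR of a random matrix) plus translation
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    shift <- rnorm(3, sd = 10)
    tri2 <- t(q %*% t(tri)) + matrix(shift, 3, 3, byrow = TRUE)
    expect_equal(incircle_radius(tri2[1, ], tri2[2, ], tri2[3, ]), r,
                 tolerance = 1e-9)
    s <- runif(1, 0.1, 5)
    expect_equal(incircle_radius(s * tri[1, ], s * tri[2, ], s * tri[3, ]),
                 s * r, tolerance = 1e-9)
    sides <- c(sqrt(sum((tri[1, ] - tri[2, ])^2)),
               sqrt(sum((tri[2, ] - tri[3, ])^2)),
               sqrt(sum((tri[1, ] - tri[3, ])^2)))
    area <- 0.5 * sqrt(sum(pracma::cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])^2))
    circum <- prod(sides) / (4 * area)
    expect_lt(r, circum)
  }
})

test_that("pore series reports the four face incircles with max and mean", {
  # static regular tetrahedron, hinge vertices 6.8 nm apart
  L <- 6.8
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * L / (2 * sqrt(2))
  faces <- rbind(c(0, 1, 2), c(0, 2, 3), c(0, 3, 1), c(1, 3, 2))
  pos <- array(rep(v, 2), c(4, 3, 2))
  traj <- make_trajectory(pos)
  series <- pore_series(traj, pore_spec(faces, 4L))
  expect_equal(unlist(series[1, c("r1", "r2", "r3", "r4")], use.names = FALSE),
               rep(L / (2 * sqrt(3)), 4))
  expect_equal(series$max, series$mean)
  expect_true(all(series$max >= series$mean))

  # one face collapsed to a line: its radius is 0, max over the others
  pos2 <- pos
  pos2[4, , ] <- pos2[3, , ] + 1e-13  # vertex 4 onto vertex 3
  series2 <- pore_series(make_trajectory(pos2), pore_spec(faces, 4L))
  expect_equal(series2$r2[1], 0)   # face touching the collapsed vertex pair
  expect_gt(series2$max[1], 1.9)   # face 1 (vertices 1,2,3) survives
})

test_that("leakage uses a strict cargo-radius threshold", {
  series <- data.frame(max = c(1.9, 2.0, 1.963))
  expect_equal(leakage_frames(series, 2.3), integer(0))
  expect_equal(leakage_frames(series, 1.0), 1:3)
  expect_equal(leakage_frames(data.frame(max = rep(1.963, 5)), 1.963), integer(0))
  expect_error(leakage_frames(series, 0), "positive")
})

test_that("pore spec validates its shape and indices", {
  expect_error(pore_spec(matrix(0L, 3, 3)), "4 faces")
  expect_error(pore_spec(rbind(c(0, 0, 1), c(0, 1, 2), c(0, 1, 3), c(1, 2, 3))),
               "distinct")
  expect_error(pore_spec(matrix(c(0:10, 99L), 4, 3), n_nucleotides = 12L),
               "out of range")
})
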
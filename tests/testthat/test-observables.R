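# Observables: Rg, gyration-tensor shape factor, P2 order parameter and
# profiles, landmark detection.

test_that("radius of gyration matches closed forms", {
  expect_equal(radius_of_gyration(rbind(c(1, 2, 3))), 0)
  # two beads separated by d: Rg = d/2
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(0, 3, 0))), 1.5)
  # unit square corners: sqrt(1/2)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(radius_of_gyration(sq), sqrt(0.5))
})

test_that("wrapped coordinates are detected and rejected", {
  pos <- rbind(c(0.2, 5, 5), c(9.8, 5, 5)) # a 0.4-long bond written wrapped
  expect_error(radius_of_gyration(pos, box = c(10, 10, 10)), "wrapped")
  expect_error(shape_factor(rbind(pos, c(0.2, 6, 5)), box = c(10, 10, 10)),
               "wrapped")
})

test_that("shape factor hits its analytic landmark values", {
  # collinear rod: delta = 1
  rod <- make_fixture("ANALYTIC_ROD", n = 50, length = 10, seed = 2)
  gy <- shape_factor(rod$positions)
  expect_equal(gy$delta, 1, tolerance = 1e-10)
  # equal eigenvalues (regular octahedron vertices): delta = 0
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  expect_equal(shape_factor(oct)$delta, 0, tolerance = 1e-12)
  # planar ring, two equal in-plane eigenvalues: delta = 1 - 3/4 = 0.25
  ring <- make_fixture("ANALYTIC_RING", n = 100, radius = 3, seed = 2)
  expect_equal(shape_factor(ring$positions)$delta, 0.25, tolerance = 1e-10)
  # eigenvalues sum to Rg^2
  expect_equal(sum(gy$eigenvalues), gy$Rg^2, tolerance = 1e-12)
  expect_error(shape_factor(matrix(1, 4, 3)), "coincide")
})

test_that("Rg and delta agree with direct-summation oracles on random clouds", {
  set.seed(41)
  for (rep in 1:100) {
    pos <- matrix(rnorm(3 * 30), 30, 3)
    # brute-force Rg: explicit loop over squared distances to the mean
    m <- colMeans(pos)
    acc <- 0
    for (i in 1:30) acc <- acc + sum((pos[i, ] - m)^2)
    expect_equal(radius_of_gyration(pos), sqrt(acc / 30), tolerance = 1e-12)
    # delta from the explicit 3x3 tensor, no shortcut
    S <- matrix(0, 3, 3)
    for (i in 1:30) S <- S + tcrossprod(pos[i, ] - m)
    ev <- eigen(S / 30, symmetric = TRUE)$values
    d_oracle <- 1 - 3 * (ev[1] * ev[2] + ev[2] * ev[3] + ev[1] * ev[3]) /
      sum(ev)^2
    expect_equal(shape_factor(pos)$delta, d_oracle, tolerance = 1e-12)
  }
})

test_that("delta is invariant under rigid motion, Rg under permutation", {
  set.seed(43)
  pos <- matrix(rnorm(60), 20, 3)
  base <- shape_factor(pos)
  for (rep in 1:10) {
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    moved <- pos %*% R + matrix(rnorm(3), 20, 3, byrow = TRUE)
    expect_equal(shape_factor(moved)$delta, base$delta, tolerance = 1e-10)
    expect_equal(radius_of_gyration(pos[sample(20), ]),
                 base$Rg, tolerance = 1e-12)
  }
})

test_that("P2 order parameter covers the aligned, planar and isotropic cases", {
  expect_equal(order_parameter(rbind(c(0, 0, 2), c(0, 0, -1))), 1)
  expect_equal(order_parameter(rbind(c(1, 1, 0), c(-3, 0.5, 0))), -0.5)
  # isotropic directions: mean near zero
  set.seed(47)
  u <- matrix(rnorm(3e5), 1e5, 3)
  expect_lt(abs(order_parameter(u)), 0.01)
  expect_error(order_parameter(rbind(c(0, 0, 0))), "zero chain vector")
  # bounds hold for arbitrary vector sets
  for (rep in 1:20) {
    v <- matrix(rnorm(30), 10, 3)
    p <- order_parameter(v)
    expect_gte(p, -0.5)
    expect_lte(p, 1)
  }
})

test_that("order profile reports aligned membranes as 1 and flags empty bins", {
  sys <- make_fixture("ALIGNED_MEMBRANE", seed = 3)
  prof <- order_profile(sys, bin_width = 3)
  expect_true(all(prof$p2[prof$occupied] == 1))
  expect_true(all(prof$occupied)) # membrane spans the whole x range
  expect_equal(sum(prof$n_chains), nrow(sys$topology$tails))
  expect_error(order_profile(sys, bin_width = 100), "bin_width")
})

test_that("an in-plane-flattened region reports -0.5 in its bins only", {
  sys <- make_fixture("ALIGNED_MEMBRANE", seed = 3)
  # flatten every tail whose midpoint lies in x in [0, 3): lay it along +y
  tails <- sys$topology$tails
  p <- sys$state$positions
  for (r in seq_len(nrow(tails))) {
    first <- tails[r, "first"]; last <- tails[r, "last"]
    if (p[first, 1] < 3) {
      nb <- last - first + 1
      p[first:last, ] <- cbind(rep(p[first, 1], nb),
                               p[first, 2] + 0.3 * (seq_len(nb) - 1),
                               rep(p[first, 3], nb))
    }
  }
  sys$state$positions <- p
  prof <- order_profile(sys, bin_width = 3)
  expect_equal(prof$p2[1], -0.5)
  expect_true(all(prof$p2[-1][prof$occupied[-1]] == 1))
})

test_that("a freshly built patch has a spatially uniform order profile", {
  sys <- make_fixture("BILAYER_PATCH", seed = 6)
  prof <- order_profile(sys, bin_width = 3)
  dev <- abs(prof$p2[prof$occupied] - mean(prof$p2[prof$occupied]))
  expect_lt(max(dev), 0.1)
})

test_that("landmark detection recovers constructed T1 and T2", {
  # |sin| over one period has its interior minimum at t = pi
  t <- seq(0.05, 2 * pi, by = 0.05)
  lm <- detect_landmarks(t, abs(sin(t)), smoothing_window = 0.25)
  expect_equal(lm$T1, pi, tolerance = 0.3)
  expect_equal(lm$Te, max(t))

  # strictly decreasing: no interior landmarks, Te = end
  lm2 <- detect_landmarks(seq(1, 50), 100 - seq(1, 50), smoothing_window = 3)
  expect_true(is.na(lm2$T1))
  expect_true(is.na(lm2$T2))
  expect_equal(lm2$Te, 50)

  # decline-rise-settle trace: both landmarks within one smoothing window
  tr <- make_observable_trace("paper_like_decline_rise", noise = 0.02,
                              seed = 9, T1 = 15, T2 = 45, Te = 75)
  lm3 <- detect_landmarks(tr$time, tr$value, smoothing_window = 5)
  expect_lt(abs(lm3$T1 - 15), 5)
  expect_lt(abs(lm3$T2 - 45), 5)
  expect_true(lm3$T1 < lm3$T2 && lm3$T2 < lm3$Te)
})

test_that("brush gyration treats the whole molecule as one object", {
  sys <- make_fixture("MINI_BRUSH_ON_PATCH", seed = 8)
  gy <- brush_gyration(sys)
  expect_equal(gy$Rg,
               radius_of_gyration(
                 unwrapped_positions(sys)[sys$topology$brush, ]),
               tolerance = 1e-12)
  expect_true(gy$delta >= 0 && gy$delta <= 1)
})
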
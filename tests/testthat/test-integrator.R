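# Integration: modified velocity-Verlet, cell-list neighbor search, periodic
# boundaries, substrate beads, determinism.

test_that("a free bead with no neighbors moves ballistically", {
  sys <- dpd_system(rbind(c(2, 2, 2)), box = c(5, 5, 5),
                    velocities = rbind(c(0.3, -0.1, 0.2)))
  out <- dpd_step(sys, 100, seed = 1)
  expect_equal(unwrapped_positions(out)[1, ],
               c(2, 2, 2) + 100 * 0.005 * c(0.3, -0.1, 0.2), tolerance = 1e-12)
  expect_equal(out$state$velocities[1, ], c(0.3, -0.1, 0.2))
})

test_that("trajectories are bit-identical for the same seed and chunking-invariant", {
  sys <- random_fluid(200, L = c(6, 6, 6), seed = 3)
  a <- dpd_step(sys, 200, seed = 11)
  b <- dpd_step(sys, 200, seed = 11)
  expect_identical(a$state$positions, b$state$positions)
  expect_identical(a$state$velocities, b$state$velocities)
  # a chunked run continues the noise stream: same physics, with only
  # neighbor-list summation order (hence rounding) differing at the split
  c1 <- dpd_step(dpd_step(sys, 120, seed = 11), 80, seed = 11)
  expect_equal(a$state$positions, c1$state$positions, tolerance = 1e-9)
  c2 <- dpd_step(dpd_step(sys, 120, seed = 11), 80, seed = 11)
  expect_identical(c1$state$positions, c2$state$positions)
  # different seed diverges
  d <- dpd_step(sys, 200, seed = 12)
  expect_false(identical(a$state$positions, d$state$positions))
})

test_that("fixed beads never move and keep zero velocity", {
  sys <- random_fluid(300, L = c(6, 6, 6), seed = 5)
  sys$topology$fixed <- 1:30
  sys$state$velocities[1:30, ] <- 0
  out <- dpd_step(sys, 300, seed = 2)
  expect_identical(out$state$positions[1:30, ], sys$state$positions[1:30, ])
  expect_identical(out$state$images[1:30, ], sys$state$images[1:30, ])
  expect_true(all(out$state$velocities[1:30, ] == 0))
  # the free beads did move
  expect_false(identical(out$state$positions[31:300, ],
                         sys$state$positions[31:300, ]))
})

test_that("cell-list pair enumeration equals the brute-force scan", {
  set.seed(8)
  for (rep in 1:5) {
    pos <- cbind(runif(100, 0, 10), runif(100, 0, 10), runif(100, 0, 10))
    cl <- neighbor_pairs(pos, c(10, 10, 10), rc = 1)
    bf <- neighbor_pairs(pos, c(10, 10, 10), rc = 1, brute = TRUE)
    expect_identical(pair_key(cl), pair_key(bf))
  }
  # beads straddling a periodic face at 0.3 through the boundary
  pos <- rbind(c(0.1, 5, 5), c(9.9, 5, 5))
  expect_equal(nrow(neighbor_pairs(pos, c(10, 10, 10), rc = 1)), 1)
  # empty system
  expect_equal(nrow(neighbor_pairs(matrix(numeric(), 0, 3), c(5, 5, 5))), 0)
})

test_that("forces are invariant under lattice translations (PBC consistency)", {
  sys <- random_fluid(150, L = c(7, 7, 7), seed = 13)
  f0 <- total_forces(sys, seed = 4, step = 2)
  shifted <- sys
  shifted$state$positions <- (sys$state$positions +
                                matrix(c(7, 14, -7), 150, 3, byrow = TRUE)) %% 7
  f1 <- total_forces(shifted, seed = 4, step = 2)
  expect_equal(f0, f1, tolerance = 1e-12)
})

test_that("the conservative limit conserves energy (symplectic check)", {
  # sigma = gamma = 0: plain velocity Verlet on soft spheres
  params <- dpd_params(gamma = 0, sigma = 0, dt = 0.005)
  sys <- random_fluid(300, L = c(6, 6, 6), seed = 17, params = params)
  e0 <- potential_energy(sys) + 0.5 * sum(sys$state$velocities^2)
  out <- dpd_step(sys, 10000, seed = 1)
  e1 <- potential_energy(out) + 0.5 * sum(out$state$velocities^2)
  expect_lt(abs(e1 - e0) / abs(e0), 0.01)
})

test_that("momentum is conserved without pulling or fixed beads", {
  sys <- random_fluid(500, L = c(7, 7, 7), seed = 23)
  p <- total_momentum(sys)
  for (k in 1:20) {
    sys <- dpd_step(sys, 1, seed = 9)
    p2 <- total_momentum(sys)
    expect_lt(max(abs(p2 - p)), 1e-10)
    p <- p2
  }
})

test_that("the thermostat holds kBT = 1 in a small pure fluid", {
  sys <- make_fixture("PURE_FLUID", seed = 4, box = box_spec(6, 6, 6, rho = 3))
  sys <- dpd_step(sys, 1000, seed = 31) # relax the random-placement transient
  out <- run_dpd(sys, 2000, seed = 31, stride = 100)
  expect_equal(mean(out$samples$temperature), 1, tolerance = 0.05)
})

test_that("run_dpd invokes samplers at the stride and streams a trajectory", {
  sys <- random_fluid(50, L = c(5, 5, 5), seed = 2)
  tf <- tempfile(fileext = ".xyz")
  out <- run_dpd(sys, 1000, seed = 3, stride = 200, trajectory = tf)
  expect_equal(nrow(out$samples), 5)
  expect_equal(out$samples$time, (1:5) * 200 * 0.005)
  expect_equal(length(read_xyz(tf)), 5)
  unlink(tf)
})

test_that("an exploding configuration raises an instability error", {
  sys <- dpd_system(rbind(c(1, 1, 1)), box = c(5, 5, 5),
                    velocities = rbind(c(1e4, 0, 0)))
  expect_error(dpd_step(sys, 10, seed = 1), "instability")
})

test_that("physical time maps to steps through dt", {
  # 120 tau at dt = 0.005 is 24,000 steps
  params <- dpd_params()
  expect_equal(120 / params$dt, 24000)
  sys <- random_fluid(20, L = c(5, 5, 5), seed = 1)
  out <- dpd_step(sys, 200, seed = 1)
  expect_equal(out$state$time, 1)
})
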
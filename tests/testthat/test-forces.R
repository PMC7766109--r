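# Force terms: weight function, conservative/dissipative/random pair forces,
# bonds, angles, pulling, and their invariants.

test_that("weight function is linear inside the cutoff and zero beyond", {
  expect_equal(weight_function(0), 1)
  expect_equal(weight_function(1), 0)
  expect_equal(weight_function(0.5), 0.5)
  expect_equal(weight_function(1.7), 0)
  expect_equal(weight_function(c(0.25, 2), rc = 2), c(0.875, 0))
  expect_error(weight_function(-0.1), "negative")
})

test_that("conservative pair force has magnitude a w(r) with the sign of a", {
  sys <- two_beads(0.5)
  f <- pair_forces(sys, include = "conservative")
  # a = 25 between solvent beads: repulsion 12.5 along x
  expect_equal(f[1, ], c(-12.5, 0, 0))
  expect_equal(f[2, ], c(12.5, 0, 0))

  # adsorption entry aBM = -5: attraction of magnitude 2.5
  sys2 <- two_beads(0.5, species = c(3L, 1L), table = interaction_table(abm = -5))
  f2 <- pair_forces(sys2, include = "conservative")
  expect_equal(f2[1, ], c(2.5, 0, 0))
  expect_equal(f2[2, ], c(-2.5, 0, 0))
})

test_that("beads beyond the cutoff contribute exactly zero", {
  sys <- two_beads(1.2, vel = matrix(rnorm(6), 2, 3))
  f <- pair_forces(sys, seed = 5, step = 3)
  expect_identical(unname(as.vector(f)), rep(0, 6))
})

test_that("pair forces obey Newton's third law and conserve momentum", {
  sys <- random_fluid(400, seed = 7)
  f <- pair_forces(sys, seed = 1, step = 1)
  expect_lt(max(abs(colSums(f))), 1e-10)
  # exact antisymmetry on an isolated pair
  sys2 <- two_beads(0.3, vel = matrix(rnorm(6), 2, 3))
  f2 <- pair_forces(sys2, seed = 9, step = 2)
  expect_identical(f2[1, ], -f2[2, ])
})

test_that("dissipative force opposes the radial relative velocity", {
  # beads approaching along x at relative speed 2: friction gamma w^2 (v.r)
  vel <- rbind(c(1, 0, 0), c(-1, 0, 0))
  sys <- two_beads(0.5, vel = vel)
  f <- pair_forces(sys, include = "dissipative")
  # r_hat from 2 to 1 is -x; v_12 . r_hat = 2; force on 1: -gamma w^2 * 2 * (-x)
  expect_equal(f[1, 1], -4.5 * 0.25 * (-2) * (-1))
  expect_equal(f[1, 1], -f[2, 1])
  expect_equal(f[1, 2:3], c(0, 0))
})

test_that("pair noise is symmetric, zero-mean, unit-variance and step-fresh", {
  z_ij <- brushpull:::cpp_zeta_samples(42, 1e5, 3, 17)
  z_ji <- brushpull:::cpp_zeta_samples(42, 1e5, 17, 3)
  expect_identical(z_ij, z_ji)
  # moments of the uniform zero-mean unit-variance draw, 3 standard errors
  se_mean <- 1 / sqrt(1e5)
  expect_lt(abs(mean(z_ij)), 3 * se_mean)
  se_var <- sqrt((1.8 - 1) / 1e5) # var of zeta^2 for uniform(-sqrt3, sqrt3) is 0.8
  expect_lt(abs(var(z_ij) - 1), 3 * se_var)
  expect_true(all(abs(z_ij) <= sqrt(3)))
  # redrawn every step
  expect_gt(length(unique(z_ij)), 9e4)
})

test_that("random force has the stated variance at fixed separation", {
  # single pair at r = 0.5 over many steps: var = sigma^2 w^2 / dt
  sigma <- 3; w <- 0.5; dt <- 0.005
  z <- brushpull:::cpp_zeta_samples(7, 2e4, 1, 2)
  fr <- sigma * w * z / sqrt(dt)
  expected_var <- sigma^2 * w^2 / dt
  se <- expected_var * sqrt(2.8 / length(fr)) # conservative kurtosis bound
  expect_lt(abs(mean(fr)), 3 * sqrt(expected_var / length(fr)))
  expect_lt(abs(var(fr) - expected_var), 3 * se)
  # and the full pair-force path reproduces exactly this term
  sys <- two_beads(0.5)
  f1 <- pair_forces(sys, seed = 7, step = 1, include = "random")
  expect_equal(f1[2, 1], sigma * w * z[1] / sqrt(dt))
})

test_that("bond force is harmonic in r/rs with the right sign", {
  mk <- function(r, ks, rs) {
    sys <- two_beads(r, table = interaction_table(
      overrides = list("SOLVENT:SOLVENT" = 0)))
    sys$topology$bonds <- cbind(i = 1, j = 2, ks = ks, rs = rs)
    sys
  }
  # at equilibrium: zero
  expect_equal(max(abs(bond_forces(mk(0.7, 120, 0.7)))), 0)
  # stretched to 2 rs: restoring magnitude ks, pulling the beads together
  f <- bond_forces(mk(1.4, 120, 0.7))
  expect_equal(f[1, 1], 120)   # bead 1 pulled toward bead 2 (+x)
  expect_equal(f[2, 1], -120)
  # compressed to rs/2: push apart with magnitude ks/2
  f2 <- bond_forces(mk(0.25, 200, 0.5))
  expect_equal(f2[1, 1], -100)
  expect_equal(f2[2, 1], 100)
})

test_that("angle force vanishes at equilibrium and matches the energy", {
  sys <- angle_triple(pi, ktheta = 4.5, theta0 = pi)
  expect_lt(max(abs(angle_forces(sys))), 1e-9)
  # bending a 2*pi/3 junction straight costs ktheta (pi/3)^2
  sys2 <- angle_triple(pi, ktheta = 6, theta0 = 2 * pi / 3)
  expect_equal(potential_energy(sys2), 6 * (pi / 3)^2, tolerance = 1e-12)
})

test_that("angle forces equal the numerical gradient of the potential", {
  set.seed(31)
  h <- 1e-6
  for (case in 1:100) {
    theta <- runif(1, 0.3, pi - 0.05)
    th0 <- sample(c(pi, 2 * pi / 3), 1)
    sys <- angle_triple(theta, ktheta = runif(1, 1, 8), theta0 = th0,
                        arm = runif(1, 1.2, 2))
    f <- angle_forces(sys)
    # central differences on each coordinate of each bead
    num <- matrix(0, 3, 3)
    for (b in 1:3) for (d in 1:3) {
      up <- sys; up$state$positions[b, d] <- up$state$positions[b, d] + h
      dn <- sys; dn$state$positions[b, d] <- dn$state$positions[b, d] - h
      num[b, d] <- -(potential_energy(up) - potential_energy(dn)) / (2 * h)
    }
    expect_lt(max(abs(f - num)), 1e-6)
    # net force and torque of the triple vanish
    expect_lt(max(abs(colSums(f))), 1e-9)
    com <- colMeans(sys$state$positions)
    torque <- colSums(t(vapply(1:3, function(b) {
      r <- sys$state$positions[b, ] - com
      c(r[2] * f[b, 3] - r[3] * f[b, 2],
        r[3] * f[b, 1] - r[1] * f[b, 3],
        r[1] * f[b, 2] - r[2] * f[b, 1])
    }, numeric(3))))
    expect_lt(max(abs(torque)), 1e-9)
  }
})

test_that("degenerate bonded geometries are rejected", {
  sys <- two_beads(0.5)
  sys$state$positions[2, ] <- sys$state$positions[1, ]
  sys$topology$bonds <- cbind(i = 1, j = 2, ks = 100, rs = 0.5)
  expect_error(bond_forces(sys), "zero-length bond")

  tri <- angle_triple(pi / 2)
  tri$state$positions[1, ] <- tri$state$positions[2, ]
  expect_error(angle_forces(tri), "zero-length arm")
})

test_that("pulling force acts along +x on the selection only", {
  f <- pulling_force(1:1080, 1.7, 2000)
  expect_equal(sum(f[, 1]), 1.7 * 1080)
  expect_equal(sum(abs(f[, 2:3])), 0)
  expect_equal(sum(abs(f[1081:2000, ])), 0)
  # per-bead magnitude
  f1 <- pulling_force(5, 2.3, 10)
  expect_equal(f1[5, ], c(2.3, 0, 0))
  # F = 0 is the identity on the accumulator
  expect_equal(pulling_force(1:10, 0, 10), matrix(0, 10, 3))
  expect_warning(pulling_force(integer(), 1, 10), "empty selection")
})
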
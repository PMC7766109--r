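# Topology builders: bottlebrush, supported bilayer, solvent fill, assembly.

test_that("bottlebrush bead, bond and angle counts follow the architecture", {
  # full-scale brush: 100 + 98 * 10 beads
  b <- build_bottlebrush(brush_spec(100, 98, 10))
  expect_equal(nrow(b$positions), 1080)
  expect_equal(length(b$species), 1080)

  # smallest legal brush
  b3 <- build_bottlebrush(brush_spec(3, 1, 1))
  expect_equal(nrow(b3$positions), 4)
  expect_equal(nrow(b3$bonds), 3)
  expect_equal(nrow(b3$angles), 1)

  # independent count oracle: bonds = backbone links + per-sidechain links
  NM <- 10; nS <- 8; NS <- 3
  expected_bonds <- (NM - 1) + nS * (1 + (NS - 1))
  b10 <- build_bottlebrush(brush_spec(NM, nS, NS))
  expect_equal(nrow(b10$positions), 34)
  expect_equal(nrow(b10$bonds), expected_bonds)
  # no duplicate bonds, no self bonds
  key <- paste(pmin(b10$bonds[, 1], b10$bonds[, 2]),
               pmax(b10$bonds[, 1], b10$bonds[, 2]))
  expect_equal(anyDuplicated(key), 0L)
  expect_true(all(b10$bonds[, 1] != b10$bonds[, 2]))
})

test_that("bottlebrush layout separates beads and grafts interior sites only", {
  b <- build_bottlebrush(brush_spec(12, 10, 4), row_length = 5L)
  d <- as.matrix(dist(b$positions))
  diag(d) <- Inf
  expect_gte(min(d), 0.1)
  # each interior backbone bead carries exactly one graft bond to a sidechain
  side_start <- 13L
  graft <- b$bonds[b$bonds[, 2] >= side_start & b$bonds[, 1] < side_start, ]
  expect_equal(sort(graft[, 1]), 2:11)
  # species split
  expect_equal(sum(b$species == 3L), 12)
  expect_equal(sum(b$species == 4L), 40)
})

test_that("mismatched sidechain count is rejected", {
  expect_error(brush_spec(10, 7, 3), "nS must be NM - 2")
})

test_that("bilayer counts, fixed beads and junction angles are correct", {
  box <- box_spec(10, 10, 14, rho = 3)
  m <- build_bilayer(box, lipid_spec(3, 4), area_per_lipid = 1, seed = 5)
  n_lipids <- 200 # 2 leaflets x 10 x 10 lattice
  expect_equal(nrow(m$positions), n_lipids * (3 + 2 * 4))
  # substrate rule: two fixed head beads per lower-leaflet lipid
  expect_equal(length(m$fixed), 2 * 100)
  expect_true(all(m$species[m$fixed] == 1L))
  # fixed beads are the lowest ones
  expect_lt(max(m$positions[m$fixed, 3]), min(2, min(m$positions[-m$fixed, 3]) + 1.5))

  # angle rule: triples mixing head and tail species sit at 2*pi/3, pure at pi
  sp <- matrix(m$species[m$angles[, 1:3]], ncol = 3)
  mixed <- sp[, 1] != sp[, 2] | sp[, 2] != sp[, 3]
  expect_equal(unname(m$angles[, "theta0"]), ifelse(mixed, 2 * pi / 3, pi))
  # species counts
  expect_equal(sum(m$species == 1L), 3 * n_lipids)
  expect_equal(sum(m$species == 2L), 2 * 4 * n_lipids)
})

test_that("initial bond lengths sit at their equilibrium values", {
  box <- box_spec(8, 8, 14, rho = 3)
  m <- build_bilayer(box, seed = 9)
  sys <- dpd_system(m$positions, box, species = m$species, bonds = m$bonds)
  expect_true(audit_topology(sys))
  # direct scan: every bond exactly rs up to wrap rounding
  p <- sys$state$positions
  L <- sys$state$box
  d <- p[m$bonds[, 1], ] - p[m$bonds[, 2], ]
  for (k in 1:3) d[, k] <- d[, k] - L[k] * round(d[, k] / L[k])
  expect_equal(sqrt(rowSums(d^2)), unname(m$bonds[, "rs"]), tolerance = 1e-10)
})

test_that("bilayer rebuild with the same seed is bit-identical", {
  box <- box_spec(8, 8, 14, rho = 3)
  m1 <- build_bilayer(box, seed = 11)
  m2 <- build_bilayer(box, seed = 11)
  expect_identical(m1$positions, m2$positions)
  m3 <- build_bilayer(box, seed = 12)
  expect_false(identical(m1$positions, m3$positions))
})

test_that("interaction table has the study defaults and stays symmetric", {
  a <- interaction_table(abm = -5)
  expect_equal(a["HEAD", "HEAD"], 25)
  expect_equal(a["TAIL", "TAIL"], 25)
  expect_equal(a["HEAD", "TAIL"], 100)
  expect_equal(a["BRUSH_BACKBONE", "BRUSH_BACKBONE"], 15)
  expect_equal(a["BRUSH_BACKBONE", "BRUSH_SIDE"], 50)
  expect_equal(a["BRUSH_SIDE", "HEAD"], -5)
  expect_equal(a["BRUSH_BACKBONE", "HEAD"], -5)
  expect_equal(a["SOLVENT", "TAIL"], 100)
  expect_equal(interaction_table(abm = -20)["BRUSH_SIDE", "HEAD"], -20)

  b <- interaction_table(overrides = list("HEAD:SOLVENT" = 30))
  expect_equal(b["HEAD", "SOLVENT"], 30)
  expect_equal(b["SOLVENT", "HEAD"], 30)
  expect_identical(unclass(b), t(unclass(b)))
  expect_error(interaction_table(overrides = list("HEAD:WATER" = 1)),
               "unknown species pair")
})

test_that("solvent fill reaches rho V and respects the exclusion shell", {
  box <- box_spec(10, 10, 10, rho = 3)
  s <- fill_solvent(box, seed = 3)
  expect_equal(nrow(s), 3000)

  occ <- matrix(runif(3000, 0, 10), 1000, 3)
  s2 <- fill_solvent(box, occ, seed = 4)
  expect_equal(nrow(s2), 2000)
  # exclusion: no solvent bead within 0.5 of an occupied bead
  pairs <- neighbor_pairs(rbind(occ, s2), c(10, 10, 10), rc = 0.5)
  cross <- xor(pairs[, 1] <= 1000, pairs[, 2] <= 1000)
  expect_equal(sum(cross), 0)

  expect_error(fill_solvent(box_spec(3, 3, 3, rho = 3),
                            matrix(runif(300), 100, 3) * 0.03 + 5),
               "exceeds rho")
})

test_that("assembly conserves counts, thermalizes, and places the brush low-x", {
  box <- box_spec(12, 12, 14, rho = 3)
  m <- build_bilayer(box, seed = 21)
  br <- build_bottlebrush(brush_spec(10, 8, 3), row_length = 2L)
  sys <- assemble_system(membrane = m, brush = br, solvent = TRUE,
                         table = interaction_table(), box = box, seed = 21)
  expect_equal(n_beads(sys), round(3 * 12 * 12 * 14))
  expect_equal(length(sys$topology$brush), 34)
  # merged counts by species
  expect_equal(sum(sys$topology$species == 1L), sum(m$species == 1L))
  expect_equal(sum(sys$topology$species %in% c(3L, 4L)), 34)
  # initial kinetic temperature ~ kBT
  expect_equal(kinetic_temperature(sys), 1, tolerance = 0.05)
  # net momentum of free beads removed
  expect_lt(max(abs(total_momentum(sys))), 1e-10)
  # placement rule
  brush_com <- mean(sys$state$positions[sys$topology$brush, 1])
  expect_lt(brush_com, 0.1 * box$Lx)
  # brush sits above the membrane
  expect_gt(min(sys$state$positions[sys$topology$brush, 3]),
            max(sys$state$positions[sys$topology$fixed, 3]))
})

test_that("fluctuation-dissipation violations are rejected at construction", {
  expect_error(dpd_params(gamma = 2, sigma = 3), "fluctuation-dissipation")
  expect_silent(dpd_params(gamma = 4.5, sigma = 3, kBT = 1))
  expect_equal(dpd_params(gamma = 2)$sigma, 2)
})
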
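# Synthetic fixtures: determinism and analytic ground truths.

test_that("fixtures regenerate bit-identically from (spec, seed)", {
  for (kind in c("PURE_FLUID", "ANALYTIC_ROD", "ISOTROPIC_CLOUD")) {
    a <- make_fixture(kind, seed = 5)
    b <- make_fixture(kind, seed = 5)
    expect_identical(a, b)
  }
  p1 <- make_fixture("BILAYER_PATCH", seed = 5)
  p2 <- make_fixture("BILAYER_PATCH", seed = 5)
  expect_identical(p1$state, p2$state)
  expect_false(identical(make_fixture("PURE_FLUID", seed = 5)$state$positions,
                         make_fixture("PURE_FLUID", seed = 6)$state$positions))
})

test_that("analytic rod truth matches brute-force recomputation", {
  rod <- make_fixture("ANALYTIC_ROD", n = 50, length = 10, seed = 3)
  # recompute Rg by direct summation here, independently of the bundle
  pos <- rod$positions
  m <- colMeans(pos)
  acc <- 0
  for (i in seq_len(nrow(pos))) acc <- acc + sum((pos[i, ] - m)^2)
  expect_equal(rod$truth$Rg, sqrt(acc / nrow(pos)), tolerance = 1e-12)
  # and the closed form L/2 * sqrt((n^2-1)/(3 n^2)) with L = n * spacing
  expect_equal(rod$truth$Rg, rod$truth$Rg_closed_form, tolerance = 1e-12)
  expect_equal(shape_factor(pos)$delta, rod$truth$delta, tolerance = 1e-10)
})

test_that("analytic ring truth matches direct evaluation", {
  ring <- make_fixture("ANALYTIC_RING", n = 200, radius = 2.5, seed = 3)
  expect_equal(radius_of_gyration(ring$positions), ring$truth$Rg,
               tolerance = 1e-12)
  expect_equal(ring$truth$Rg, 2.5, tolerance = 1e-12)
  expect_equal(shape_factor(ring$positions)$delta, ring$truth$delta,
               tolerance = 1e-10)
})

test_that("a large isotropic cloud is nearly spherical", {
  cloud <- make_fixture("ISOTROPIC_CLOUD", n = 1e4, seed = 7)
  expect_lt(shape_factor(cloud$positions)$delta, cloud$truth$delta_max)
})

test_that("physical fixtures carry the right sizes and species", {
  fl <- make_fixture("PURE_FLUID", seed = 2)
  expect_equal(n_beads(fl), 3000)
  expect_true(all(fl$topology$species == 5L))

  ch <- make_fixture("SINGLE_CHAIN", seed = 2)
  expect_equal(sum(ch$topology$species == 3L), 20)
  expect_equal(n_beads(ch), round(3 * 12 * 8 * 8))

  mb <- make_fixture("MINI_BRUSH_ON_PATCH", seed = 2)
  expect_equal(length(mb$topology$brush), 10 + 8 * 3)
  expect_gt(length(mb$topology$fixed), 0)
})

test_that("synthetic traces encode their constructed landmarks", {
  tr <- make_observable_trace("paper_like_decline_rise", noise = 0, seed = 1,
                              T1 = 15, T2 = 45, Te = 75)
  expect_equal(attr(tr, "T1"), 15)
  expect_equal(attr(tr, "T2"), 45)
  # the construction really has its extrema there
  expect_equal(tr$time[which.min(tr$value)], 15, tolerance = 0.5)
  idx <- which(tr$time > 15)
  expect_equal(tr$time[idx][which.max(tr$value[idx])], 45, tolerance = 0.5)

  fl <- make_observable_trace("flat", noise = 0, seed = 1)
  expect_true(is.na(attr(fl, "T1")))
  lm <- detect_landmarks(fl$time, fl$value, smoothing_window = 5)
  expect_true(is.na(lm$T1) && is.na(lm$T2))

  mono <- make_observable_trace("monotone", seed = 1)
  lm2 <- detect_landmarks(mono$time, mono$value, smoothing_window = 5)
  expect_true(is.na(lm2$T1))
  expect_equal(lm2$Te, attr(mono, "Te"))
})
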
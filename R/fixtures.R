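# Synthetic fixtures: miniature physical systems and analytic bead
# configurations with exactly known observables, regenerated from (spec, seed)
# at test time. Analytic ground truths are computed here by direct summation
# (explicit loops), independent of the observables module.

# brute-force Rg by explicit double loop over squared distances to the mean
brute_rg <- function(pos) {
  m <- colMeans(pos)
  acc <- 0
  for (i in seq_len(nrow(pos)))
    acc <- acc + sum((pos[i, ] - m)^2)
  sqrt(acc / nrow(pos))
}

#' Generate a test fixture
#'
#' Deterministic miniature systems and analytic configurations:
#' \describe{
#'   \item{PURE_FLUID}{solvent-only box at density rho (default 10x10x10,
#'     3000 beads), Maxwell velocities.}
#'   \item{SINGLE_CHAIN}{a 20-bead linear chain in solvent.}
#'   \item{BILAYER_PATCH}{a small supported bilayer with solvent.}
#'   \item{MINI_BRUSH_ON_PATCH}{the patch plus an NM = 10 bottlebrush.}
#'   \item{ANALYTIC_ROD}{collinear equispaced beads; ground-truth delta = 1
#'     and Rg from direct summation.}
#'   \item{ANALYTIC_RING}{beads on a planar circle; ground-truth delta = 0.25
#'     and Rg = radius (direct summation).}
#'   \item{ALIGNED_MEMBRANE}{a bilayer built with zero tail tilt; every
#'     occupied order-profile bin is exactly 1.}
#'   \item{ISOTROPIC_CLOUD}{an isotropic Gaussian cloud; delta near 0.}
#' }
#'
#' @param kind One of the fixture kinds above.
#' @param seed Integer seed; every fixture is bit-reproducible from
#'   `(kind, parameters, seed)`.
#' @param n Bead count for ROD/RING/CLOUD kinds.
#' @param length Rod length (rc).
#' @param radius Ring radius (rc).
#' @param box A [box_spec()] for the physical kinds.
#' @param abm Adsorption parameter for MINI_BRUSH_ON_PATCH.
#' @return For physical kinds a `dpd_system`; for analytic kinds a list with
#'   `positions` and `truth` (exact expected observables).
#' @export
make_fixture <- function(kind = c("PURE_FLUID", "SINGLE_CHAIN",
                                  "BILAYER_PATCH", "MINI_BRUSH_ON_PATCH",
                                  "ANALYTIC_ROD", "ANALYTIC_RING",
                                  "ALIGNED_MEMBRANE", "ISOTROPIC_CLOUD"),
                         seed = 1, n = 50, length = 10, radius = 3,
                         box = NULL, abm = -5) {
  kind <- match.arg(kind)
  set.seed(seed)
  switch(kind,
    PURE_FLUID = {
      if (is.null(box)) box <- box_spec(10, 10, 10, rho = 3)
      assemble_system(membrane = NULL, brush = NULL, solvent = TRUE,
                      table = interaction_table(), box = box, seed = seed)
    },
    SINGLE_CHAIN = {
      if (is.null(box)) box <- box_spec(12, 8, 8, rho = 3)
      chain <- chain_fragment(20L, rs = 0.5, origin = c(1, box$Ly / 2, box$Lz / 2))
      assemble_system(membrane = chain, brush = NULL, solvent = TRUE,
                      table = interaction_table(), box = box, seed = seed)
    },
    BILAYER_PATCH = {
      if (is.null(box)) box <- box_spec(12, 12, 14, rho = 3)
      membrane <- build_bilayer(box, seed = seed)
      assemble_system(membrane = membrane, brush = NULL, solvent = TRUE,
                      table = interaction_table(abm = abm), box = box,
                      seed = seed)
    },
    MINI_BRUSH_ON_PATCH = {
      if (is.null(box)) box <- box_spec(12, 12, 14, rho = 3)
      membrane <- build_bilayer(box, seed = seed)
      brush <- build_bottlebrush(brush_spec(10, 8, 3), row_length = 2L)
      assemble_system(membrane = membrane, brush = brush, solvent = TRUE,
                      table = interaction_table(abm = abm), box = box,
                      seed = seed)
    },
    ANALYTIC_ROD = {
      s <- length / n
      pos <- cbind(seq_len(n) * s, 0, 0)
      # rotate to a random orientation so nothing is axis-aligned
      pos <- pos %*% random_rotation()
      list(positions = pos,
           truth = list(delta = 1, Rg = brute_rg(pos),
                        Rg_closed_form = length / 2 *
                          sqrt((n^2 - 1) / (3 * n^2))))
    },
    ANALYTIC_RING = {
      phi <- 2 * pi * (seq_len(n) - 1) / n
      pos <- cbind(radius * cos(phi), radius * sin(phi), 0)
      list(positions = pos,
           truth = list(delta = 0.25, Rg = brute_rg(pos)))
    },
    ALIGNED_MEMBRANE = {
      if (is.null(box)) box <- box_spec(12, 12, 14, rho = 3)
      membrane <- build_bilayer(box, tilt_cos_min = 1, seed = seed)
      assemble_system(membrane = membrane, brush = NULL, solvent = FALSE,
                      table = interaction_table(), box = box, seed = seed)
    },
    ISOTROPIC_CLOUD = {
      pos <- matrix(rnorm(3 * n), n, 3)
      list(positions = pos, truth = list(delta_max = 0.05))
    })
}

# linear bead chain fragment (used by the SINGLE_CHAIN fixture)
chain_fragment <- function(n, rs = 0.5, ks = 200, origin = c(0, 0, 0)) {
  pos <- cbind(origin[1] + (seq_len(n) - 1) * rs, origin[2], origin[3])
  bonds <- cbind(i = seq_len(n - 1), j = 2:n, ks = ks, rs = rs)
  angles <- if (n >= 3)
    cbind(i = seq_len(n - 2), j = 2:(n - 1), k = 3:n, ktheta = 4.5, theta0 = pi)
  else empty_angles()
  new_fragment(pos, rep(SPECIES[["BRUSH_BACKBONE"]], n), bonds, angles,
               integer(), rep(1L, n), "chain")
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3)))
}

#' Generate a synthetic observable trace with known landmarks
#'
#' Test harness for [detect_landmarks()]: builds traces whose true T1/T2 are
#' known by construction.
#'
#' @param shape `"paper_like_decline_rise"` (decline to a minimum at T1, rise
#'   to a local maximum at T2, then settle), `"monotone"` (strictly
#'   decreasing) or `"flat"`.
#' @param noise Gaussian noise standard deviation added to the trace.
#' @param seed Integer seed.
#' @param T1,T2 Constructed landmark times (tau).
#' @param Te Trace end time (tau).
#' @param dt_sample Sampling interval (tau).
#' @param v0,vmin,vmax Trace levels: start, minimum at T1, maximum at T2.
#' @return Tibble with `time` and `value`; attributes `T1`, `T2`, `Te` carry
#'   the construction ground truth (NA where undefined).
#' @export
make_observable_trace <- function(shape = c("paper_like_decline_rise",
                                            "monotone", "flat"),
                                  noise = 0, seed = 1, T1 = 15, T2 = 45,
                                  Te = 75, dt_sample = 0.5, v0 = 5,
                                  vmin = 4.2, vmax = 4.65) {
  shape <- match.arg(shape)
  set.seed(seed)
  time <- seq(dt_sample, Te, by = dt_sample)
  value <- switch(shape,
    paper_like_decline_rise = {
      stopifnot(T1 < T2, T2 < Te)
      v <- numeric(length(time))
      a <- time <= T1
      v[a] <- vmin + (v0 - vmin) * cos(pi / 2 * time[a] / T1)^2
      b <- time > T1 & time <= T2
      v[b] <- vmin + (vmax - vmin) * sin(pi / 2 * (time[b] - T1) / (T2 - T1))^2
      c3 <- time > T2
      mid <- (vmax + vmin) / 2
      v[c3] <- mid + (vmax - mid) * exp(-(time[c3] - T2) / (0.2 * (Te - T2)))
      v
    },
    monotone = v0 - (v0 - vmin) * time / Te,
    flat = rep(v0, length(time)))
  value <- value + rnorm(length(time), sd = noise)
  out <- tibble::tibble(time = time, value = value)
  attr(out, "T1") <- if (shape == "paper_like_decline_rise") T1 else NA_real_
  attr(out, "T2") <- if (shape == "paper_like_decline_rise") T2 else NA_real_
  attr(out, "Te") <- Te
  out
}
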
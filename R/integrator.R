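# Time integration: Groot-Warren modified velocity-Verlet with a cell-list
# neighbor search, periodic boundaries and immobile substrate beads.

fixed_mask <- function(system) {
  m <- logical(n_beads(system))
  m[system$topology$fixed] <- TRUE
  m
}

#' Advance the system by a number of steps
#'
#' One modified velocity-Verlet update per step: half kick, drift,
#' lambda-predicted velocities for the single force evaluation, then the final
#' velocity correction. Substrate beads exert forces but are never moved.
#' Positions are re-wrapped each step with image counts tracked. A bead
#' displacing more than half the smallest box edge in one step raises an
#' instability error.
#'
#' @param system A `dpd_system`.
#' @param steps Number of integration steps.
#' @param seed Integer seed keying the pair-noise stream (with the absolute
#'   step counter, so continuing a run reproduces a longer run bit-exactly).
#' @param pull_force Constant per-bead x-force applied to the brush beads.
#' @return The advanced `dpd_system` (clock and cached forces updated).
#' @export
dpd_step <- function(system, steps = 1L, seed = 0, pull_force = 0) {
  st <- system$state
  tp <- system$topology
  pull_idx <- integer()
  if (pull_force != 0) {
    pull_idx <- tp$brush
    if (is.null(pull_idx)) {
      warning("pulling force requested but the system has no brush")
      pull_idx <- integer()
    }
  }
  out <- cpp_run(st$positions, st$velocities, st$images, st$box,
                 species0(tp), unclass(system$table), tp$bonds, tp$angles,
                 fixed_mask(system), as.integer(pull_idx), pull_force,
                 system$params$gamma, system$params$sigma, system$params$dt,
                 system$params$lambda, as.integer(steps), seed, st$step,
                 st$forces)
  st$positions <- out$positions
  st$velocities <- out$velocities
  st$images <- out$images
  st$forces <- out$forces
  st$step <- st$step + out$steps_done
  st$time <- st$step * system$params$dt
  system$state <- st
  system
}

#' Enumerate neighbor pairs within a cutoff
#'
#' Cell-list pair search with a half stencil and periodic wrap; falls back to
#' the O(N^2) minimum-image scan when the box is under three cells along any
#' axis. With `brute = TRUE` the reference scan is used unconditionally — the
#' two paths enumerate identical pair sets.
#'
#' @param positions N x 3 matrix (wrapped coordinates).
#' @param box Length-3 box edges.
#' @param rc Cutoff radius.
#' @param brute Force the O(N^2) reference path.
#' @return Two-column integer matrix of pairs (i < j), ordered arbitrarily.
#' @export
neighbor_pairs <- function(positions, box, rc = 1, brute = FALSE) {
  cpp_pairs(positions, box, rc, brute)
}

#' Instantaneous kinetic temperature
#'
#' `2 KE / (3 N_free)` over the non-fixed beads (reduced units, so the target
#' is kBT = 1).
#'
#' @param system A `dpd_system`.
#' @return Scalar temperature.
#' @export
kinetic_temperature <- function(system) {
  free <- !fixed_mask(system)
  v <- system$state$velocities[free, , drop = FALSE]
  sum(v^2) / (3 * nrow(v))
}

default_samplers <- function() {
  list(temperature = kinetic_temperature)
}

#' Run a schedule of steps with periodic sampling
#'
#' Advances the system `steps` steps, invoking each sampler every `stride`
#' steps and collecting the results into a tidy time series. Deterministic
#' given (seed, initial state).
#'
#' @param system A `dpd_system`.
#' @param steps Total number of steps.
#' @param seed Noise-stream seed.
#' @param stride Steps between sampler invocations.
#' @param samplers Named list of functions `f(system) -> scalar` (defaults to
#'   kinetic temperature).
#' @param pull_force Per-bead pulling force on the brush.
#' @param trajectory Optional file path; if given, an XYZ frame is appended at
#'   every sampling point.
#' @return List with the advanced `system` and `samples`, a tibble with one
#'   row per sampling point (column `time` plus one column per sampler).
#' @export
run_dpd <- function(system, steps, seed = 0, stride = steps,
                    samplers = default_samplers(), pull_force = 0,
                    trajectory = NULL) {
  stopifnot(steps >= 0, stride >= 1)
  rows <- list()
  done <- 0L
  while (done < steps) {
    chunk <- min(stride, steps - done)
    system <- dpd_step(system, chunk, seed = seed, pull_force = pull_force)
    done <- done + chunk
    vals <- lapply(samplers, function(f) f(system))
    rows[[length(rows) + 1L]] <- c(list(time = system$state$time), vals)
    if (!is.null(trajectory))
      write_xyz(system, trajectory, append = TRUE)
  }
  samples <- if (length(rows)) {
    tibble::as_tibble(do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, check.names = FALSE))))
  } else {
    tibble::tibble(time = numeric())
  }
  list(system = system, samples = samples)
}
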
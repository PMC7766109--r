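# R-level surface over the C++ force kernels. Each term can be evaluated in
# isolation (the test suite exercises them against independent oracles) and
# `total_forces()` evaluates everything the integrator sees.

species0 <- function(topology) topology$species - 1L

#' DPD weight function
#'
#' The linear pair weight w(r) = 1 - r/rc for r < rc and 0 beyond the cutoff.
#'
#' @param r Distances (>= 0).
#' @param rc Cutoff radius.
#' @return Weights between 0 and 1.
#' @export
weight_function <- function(r, rc = 1) {
  if (any(r < 0)) stop("negative distance")
  pmax(0, 1 - r / rc)
}

force_call <- function(system, bonds, angles, pull_idx, pull_force, gamma,
                       sigma, seed, step, brute, velocities = NULL) {
  st <- system$state
  vel <- if (is.null(velocities)) st$velocities else velocities
  cpp_forces(st$positions, vel, st$box, species0(system$topology),
             unclass(system$table), bonds, angles, as.integer(pull_idx),
             pull_force, gamma, sigma, system$params$dt, seed, step, brute)
}

#' Nonbonded DPD pair forces
#'
#' Evaluates the conservative, dissipative and random pair terms for every
#' pair within the cutoff under the minimum-image convention. The random term
#' for pair (i, j) at a given step is a deterministic function of
#' `(seed, step, {i, j})`, so the cell-list and brute-force paths agree
#' exactly.
#'
#' @param system A `dpd_system`.
#' @param seed,step Integers keying the per-pair noise stream.
#' @param include Character subset of `c("conservative", "dissipative",
#'   "random")`.
#' @param brute If TRUE use the O(N^2) reference path instead of the cell
#'   list.
#' @return N x 3 force matrix (reduced units).
#' @export
pair_forces <- function(system, seed = 0, step = 1,
                        include = c("conservative", "dissipative", "random"),
                        brute = FALSE) {
  include <- match.arg(include, several.ok = TRUE,
                       choices = c("conservative", "dissipative", "random"))
  amat <- unclass(system$table)
  if (!"conservative" %in% include) amat[] <- 0
  gamma <- if ("dissipative" %in% include) system$params$gamma else 0
  sigma <- if ("random" %in% include) system$params$sigma else 0
  st <- system$state
  cpp_forces(st$positions, st$velocities, st$box, species0(system$topology),
             amat, empty_bonds(), empty_angles(), integer(), 0,
             gamma, sigma, system$params$dt, seed, step, brute)
}

#' Harmonic bond forces
#'
#' Per bond, adds `ks * (1 - r/rs)` along the unit separation vector on one
#' bead and its negation on the other.
#'
#' @param system A `dpd_system`.
#' @return N x 3 force matrix.
#' @export
bond_forces <- function(system) {
  zero <- matrix(0, 5, 5)
  st <- system$state
  cpp_forces(st$positions, st$velocities, st$box, species0(system$topology),
             zero, system$topology$bonds, empty_angles(), integer(), 0,
             0, 0, system$params$dt, 0, 0, TRUE)
}

#' Harmonic bending (angle) forces
#'
#' Minus the gradient of `ktheta * (theta - theta0)^2` with respect to the
#' three bead positions of each triple; each triple's net force and torque
#' vanish.
#'
#' @param system A `dpd_system`.
#' @return N x 3 force matrix.
#' @export
angle_forces <- function(system) {
  zero <- matrix(0, 5, 5)
  st <- system$state
  cpp_forces(st$positions, st$velocities, st$box, species0(system$topology),
             zero, empty_bonds(), system$topology$angles, integer(), 0,
             0, 0, system$params$dt, 0, 0, TRUE)
}

#' Constant pulling force along x
#'
#' Adds `(F, 0, 0)` to every selected bead (in the study, all brush beads;
#' F is a per-bead magnitude).
#'
#' @param selection Bead indices receiving the force.
#' @param F Per-bead force magnitude (>= 0, reduced units m rc / tau^2).
#' @param n Total number of beads (rows of the accumulator).
#' @return N x 3 force matrix.
#' @export
pulling_force <- function(selection, F, n) {
  stopifnot(F >= 0)
  if (length(selection) == 0 && F > 0)
    warning("pulling force applied to an empty selection")
  f <- matrix(0, n, 3)
  f[selection, 1] <- F
  f
}

#' Total forces on every bead
#'
#' Pair (conservative + dissipative + random), bond, angle and external
#' pulling contributions, exactly as evaluated inside one integrator step.
#'
#' @param system A `dpd_system`.
#' @param pull_force Per-bead pulling magnitude applied to the brush beads.
#' @param seed,step Noise-stream keys.
#' @param brute Use the O(N^2) pair path.
#' @return N x 3 force matrix.
#' @export
total_forces <- function(system, pull_force = 0, seed = 0, step = 1,
                         brute = FALSE) {
  tp <- system$topology
  pull_idx <- if (pull_force != 0 && !is.null(tp$brush)) tp$brush else integer()
  st <- system$state
  cpp_forces(st$positions, st$velocities, st$box, species0(tp),
             unclass(system$table), tp$bonds, tp$angles,
             as.integer(pull_idx), pull_force,
             system$params$gamma, system$params$sigma, system$params$dt,
             seed, step, brute)
}

#' Total potential energy
#'
#' Conservative pair energy `a_ij (1 - r)^2 / 2`, bond energy
#' `ks (r - rs)^2 / (2 rs)` and bending energy `ktheta (theta - theta0)^2`.
#'
#' @param system A `dpd_system`.
#' @return Scalar energy (reduced units).
#' @export
potential_energy <- function(system) {
  st <- system$state
  tp <- system$topology
  cpp_potential_energy(st$positions, st$box, species0(tp), unclass(system$table),
                       tp$bonds, tp$angles)
}

#' Count brush-head adsorption contacts
#'
#' Number of (brush bead, lipid HEAD bead) pairs within `rcut` under minimum
#' image — the package's operational measure of adsorption strength.
#'
#' @param system A `dpd_system` containing a brush.
#' @param rcut Contact radius (rc).
#' @return Integer contact count.
#' @export
brush_head_contacts <- function(system, rcut = 1) {
  tp <- system$topology
  if (is.null(tp$brush)) stop("system has no brush")
  heads <- which(tp$species == SPECIES[["HEAD"]])
  cpp_contacts(system$state$positions, system$state$box,
               as.integer(tp$brush), as.integer(heads), rcut)
}
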
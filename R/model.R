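#' Pairwise DPD repulsion table
#'
#' Builds the symmetric 5x5 matrix of maximum conservative interaction
#' parameters a_ij (reduced units, kBT/rc) between the bead species. Negative
#' entries are attractive. Defaults follow the coarse-grained membrane/brush
#' model: 25 between identical membrane species and 100 between head and tail;
#' 15 between identical brush species and 50 between backbone and sidechain;
#' the brush-head entry is the adsorption strength `abm` (-5 weak, -20 strong
#' in the two study regimes). Solvent is hydrophilic: 25 against everything
#' except lipid tails (100).
#'
#' @param abm Adsorption parameter between both brush species and lipid HEAD
#'   beads. The two study regimes are -5 (weak) and -20 (strong).
#' @param brush_tail Repulsion between brush species and lipid TAIL beads.
#' @param overrides Optional named list `list("HEAD:SOLVENT" = 30, ...)` of
#'   pair overrides; applied symmetrically.
#' @return An `interaction_table`: a symmetric numeric matrix with species
#'   dimnames.
#' @export
interaction_table <- function(abm = -5, brush_tail = 50, overrides = NULL) {
  sp <- species_levels()
  a <- matrix(NA_real_, 5, 5, dimnames = list(sp, sp))
  set <- function(s1, s2, val) {
    a[s1, s2] <<- val
    a[s2, s1] <<- val
  }
  set("HEAD", "HEAD", 25); set("TAIL", "TAIL", 25); set("HEAD", "TAIL", 100)
  set("BRUSH_BACKBONE", "BRUSH_BACKBONE", 15)
  set("BRUSH_SIDE", "BRUSH_SIDE", 15)
  set("BRUSH_BACKBONE", "BRUSH_SIDE", 50)
  set("BRUSH_BACKBONE", "HEAD", abm); set("BRUSH_SIDE", "HEAD", abm)
  set("BRUSH_BACKBONE", "TAIL", brush_tail); set("BRUSH_SIDE", "TAIL", brush_tail)
  set("SOLVENT", "SOLVENT", 25)
  set("SOLVENT", "HEAD", 25); set("SOLVENT", "TAIL", 100)
  set("SOLVENT", "BRUSH_BACKBONE", 25); set("SOLVENT", "BRUSH_SIDE", 25)
  if (!is.null(overrides)) {
    for (key in names(overrides)) {
      pair <- strsplit(key, ":", fixed = TRUE)[[1]]
      if (length(pair) != 2 || !all(pair %in% sp))
        stop("unknown species pair in override: ", key)
      set(pair[1], pair[2], overrides[[key]])
    }
  }
  structure(a, class = c("interaction_table", "matrix", "array"))
}

#' @export
print.interaction_table <- function(x, ...) {
  cat("DPD interaction table a_ij (reduced units):\n")
  print(unclass(x))
  invisible(x)
}

validate_interaction_table <- function(a) {
  if (!all(dim(a) == c(5, 5)) || anyNA(a))
    stop("interaction table must populate all 15 species pairs")
  if (!isTRUE(all.equal(unclass(a), t(unclass(a)))))
    stop("interaction table must be symmetric")
  invisible(a)
}

#' DPD thermostat and integration parameters
#'
#' The dissipative/random pair of the DPD thermostat must satisfy the
#' fluctuation-dissipation relation sigma^2 = 2 gamma kBT; violating inputs
#' are rejected. Defaults: gamma = 4.5, sigma = 3.0, kBT = 1, time step
#' dt = 0.005 tau, Groot-Warren velocity-prediction factor lambda = 0.5.
#'
#' @param gamma Dissipative strength (reduced units).
#' @param sigma Random-force strength; defaults to `sqrt(2 * gamma * kBT)`.
#' @param kBT Thermal energy (reduced; the temperature unit).
#' @param rc Pair-force cutoff (the length unit; 1 in reduced units).
#' @param dt Integration time step in tau.
#' @param lambda Velocity-prediction factor of the modified velocity-Verlet
#'   scheme, in (0, 1].
#' @return A `dpd_params` list.
#' @export
dpd_params <- function(gamma = 4.5, sigma = sqrt(2 * gamma * kBT), kBT = 1,
                       rc = 1, dt = 0.005, lambda = 0.5) {
  stopifnot(gamma >= 0, kBT > 0, rc > 0, dt > 0, lambda > 0, lambda <= 1)
  if (abs(sigma^2 - 2 * gamma * kBT) > 1e-9)
    stop("fluctuation-dissipation violation: sigma^2 must equal 2*gamma*kBT (",
         sigma^2, " != ", 2 * gamma * kBT, ")")
  structure(list(gamma = gamma, sigma = sigma, kBT = kBT, rc = rc, dt = dt,
                 lambda = lambda),
            class = "dpd_params")
}

#' Lipid architecture
#'
#' A lipid is one linear head chain of `n_head` hydrophilic beads with two
#' linear tail chains of `n_tail` hydrophobic beads each attached to the last
#' head bead. `n_head >= 3` so that the pure-head bending rule over three
#' consecutive head beads applies.
#'
#' @param n_head Beads in the head chain (>= 3).
#' @param n_tail Beads per tail chain (>= 3).
#' @return A `lipid_spec` list (the per-lipid bead count is
#'   `n_head + 2 * n_tail`).
#' @export
lipid_spec <- function(n_head = 3, n_tail = 4) {
  stopifnot(n_head >= 3, n_tail >= 3)
  structure(list(n_head = as.integer(n_head), n_tail = as.integer(n_tail),
                 n_tails = 2L),
            class = "lipid_spec")
}

#' Bottlebrush architecture
#'
#' A linear backbone of `NM` beads with one sidechain of `NS` beads grafted to
#' every backbone bead except the two chain ends, so `nS` must equal `NM - 2`.
#' The full-scale model uses NM = 100, nS = 98, NS = 10 (1080 beads).
#'
#' @param NM Backbone bead count (>= 3).
#' @param nS Number of sidechains; must be `NM - 2`.
#' @param NS Beads per sidechain (>= 1).
#' @return A `brush_spec` list.
#' @export
brush_spec <- function(NM = 100, nS = NM - 2, NS = 10) {
  stopifnot(NM >= 3, NS >= 1)
  if (nS != NM - 2)
    stop("topology inconsistency: nS must be NM - 2 (one sidechain per ",
         "interior backbone bead); got nS = ", nS, " with NM = ", NM)
  structure(list(NM = as.integer(NM), nS = as.integer(nS), NS = as.integer(NS)),
            class = "brush_spec")
}

#' Simulation box
#'
#' Orthorhombic periodic box with a global bead number density. The full-scale
#' study box is 400 x 30 x 20 rc at rho = 3 beads/rc^3.
#'
#' @param Lx,Ly,Lz Box edge lengths in rc (> 2 each).
#' @param rho Bead number density in beads/rc^3.
#' @return A `box_spec` list.
#' @export
box_spec <- function(Lx = 400, Ly = 30, Lz = 20, rho = 3) {
  stopifnot(Lx > 2, Ly > 2, Lz > 2, rho > 0)
  structure(list(Lx = Lx, Ly = Ly, Lz = Lz, rho = rho), class = "box_spec")
}

box_lengths <- function(box) c(box$Lx, box$Ly, box$Lz)

#' Reduced unit system and physical mapping
#'
#' In reduced units m = kBT = rc = 1 and the natural time unit is
#' tau = rc * sqrt(m / kBT). The physical cutoff follows from the bead volume:
#' rc_physical = (rho * Vb)^(1/3), about 0.448 nm at Vb = 0.03 nm^3 and
#' rho = 3 (commonly rounded to 0.5 nm).
#'
#' @param Vb Physical bead volume in nm^3.
#' @param rho Bead number density (beads/rc^3).
#' @param m Bead mass (reduced).
#' @param kBT Thermal energy (reduced).
#' @return A `unit_system` list with `tau` (reduced) and `rc_physical` (nm).
#' @export
unit_system <- function(Vb = 0.03, rho = 3, m = 1, kBT = 1) {
  structure(list(m = m, kBT = kBT, rc = 1,
                 tau = 1 * sqrt(m / kBT),
                 Vb = Vb, rho = rho,
                 rc_physical = (rho * Vb)^(1 / 3)),
            class = "unit_system")
}
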
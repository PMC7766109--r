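# End-to-end pulling experiments: equilibrate, pull at constant force under a
# chosen adsorption strength, record observables, detect landmark times, and
# sweep the pulling force.

#' Pulling protocol
#'
#' Constant per-bead force on every brush bead along +x, applied after an
#' equilibration phase. The study range for F is 0.8-2.4 (reduced units);
#' values outside it are accepted with a warning. The run terminates at
#' `max_time`, when the brush center of mass reaches within 5 rc of the +x
#' box edge, or when a persistent pore is detected in the membrane.
#'
#' @param F Per-bead pulling magnitude (m rc / tau^2).
#' @param abm Adsorption parameter (brush-head attraction; -5 weak, -20
#'   strong).
#' @param equilibration_steps Steps of force-free relaxation before pulling.
#' @param max_time Pulling-phase time budget (tau).
#' @param stride Steps between observable samples.
#' @param edge_margin Brush-to-edge distance that triggers termination (rc).
#' @param pore_cell Edge of the x-y pore-detection grid cells (rc).
#' @param pore_persist Consecutive samples a grid cell must stay empty of
#'   TAIL beads to flag a pore.
#' @return A `pull_protocol` list.
#' @export
pull_protocol <- function(F, abm = -5, equilibration_steps = 10000L,
                          max_time = 120, stride = 100L, edge_margin = 5,
                          pore_cell = 2, pore_persist = 5L) {
  stopifnot(F >= 0, max_time > 0, stride >= 1)
  if (F < 0.8 || F > 2.4)
    warning("pulling force ", F, " is outside the study range [0.8, 2.4]")
  structure(list(F = F, abm = abm,
                 equilibration_steps = as.integer(equilibration_steps),
                 max_time = max_time, stride = as.integer(stride),
                 edge_margin = edge_margin, pore_cell = pore_cell,
                 pore_persist = as.integer(pore_persist)),
            class = "pull_protocol")
}

membrane_intact <- function(system) {
  tp <- system$topology
  if (is.null(tp$leaflet)) return(TRUE)
  heads <- tp$species == SPECIES[["HEAD"]]
  leaf_of_bead <- tp$leaflet[tp$mol_id]
  z <- system$state$positions[, 3]
  zl <- mean(z[heads & leaf_of_bead == 1])
  zu <- mean(z[heads & leaf_of_bead == 2])
  b <- tp$bonds
  tail_len <- max(b[, "rs"]) * 4 # one tail contour length under H3T4
  (zu - zl) >= tail_len
}

#' Equilibrate a system without pulling
#'
#' Relaxes the assembled configuration with the plain DPD thermostat. After a
#' nonzero number of steps the kinetic temperature is verified to sit within
#' 5 percent of kBT = 1 and, when a membrane is present, the two leaflets
#' must remain separated (membrane intact), otherwise a model-parameter error
#' is raised. Zero steps is the identity.
#'
#' @param system A `dpd_system`.
#' @param steps Equilibration steps.
#' @param seed Noise seed.
#' @return The relaxed `dpd_system`.
#' @export
equilibrate <- function(system, steps = 10000L, seed = 0) {
  if (steps == 0) return(system)
  system <- dpd_step(system, steps, seed = seed, pull_force = 0)
  temp <- kinetic_temperature(system)
  if (abs(temp - system$params$kBT) > 0.05 * system$params$kBT)
    stop("equilibration failed: kinetic temperature ", round(temp, 3))
  if (!membrane_intact(system))
    stop("membrane disintegrated during equilibration; check model parameters")
  system
}

# x-y occupancy of TAIL beads on a grid of `cell`-sized cells
tail_occupancy <- function(system, cell) {
  L <- system$state$box
  tp <- system$topology
  tails <- tp$species == SPECIES[["TAIL"]]
  nx <- max(1L, floor(L[1] / cell)); ny <- max(1L, floor(L[2] / cell))
  p <- system$state$positions[tails, , drop = FALSE]
  cx <- pmin(nx - 1L, floor(p[, 1] / L[1] * nx))
  cy <- pmin(ny - 1L, floor(p[, 2] / L[2] * ny))
  occ <- rep(FALSE, nx * ny)
  occ[unique(cx + nx * cy) + 1L] <- TRUE
  occ
}

brush_com_x <- function(system) {
  mean(unwrapped_positions(system)[system$topology$brush, 1])
}

#' Run one constant-force pulling experiment
#'
#' Applies the protocol's per-bead force to every brush bead, sampling the
#' brush radius of gyration and shape factor, the membrane order profile and
#' its mean, the kinetic temperature and the brush-head contact count at the
#' protocol stride. Terminates at `max_time`, when the brush center of mass
#' comes within `edge_margin` of the +x box edge, or when any x-y cell of the
#' pore grid stays empty of TAIL beads for `pore_persist` consecutive
#' samples. Landmark times are detected on the Rg trace.
#'
#' @param system An equilibrated `dpd_system` (brush + membrane).
#' @param protocol A [pull_protocol()]. Its `abm` must match the system's
#'   interaction table (use [preset_system()] or rebuild the table).
#' @param seed Noise seed for the pulling phase.
#' @param smoothing_window Landmark smoothing window (tau).
#' @param profile_bin Order-profile bin width (rc).
#' @return A `dpd_pull` object: `series` (tibble of sampled observables),
#'   `profiles` (list of order-profile tibbles), `landmarks`, `termination`,
#'   the `protocol` and the final `system`.
#' @export
run_pull <- function(system, protocol, seed = 0, smoothing_window = 5,
                     profile_bin = 5) {
  stopifnot(inherits(protocol, "pull_protocol"))
  if (is.null(system$topology$brush)) stop("system has no brush to pull")
  dt <- system$params$dt
  Lx <- system$state$box[1]
  t0 <- system$state$time
  max_steps <- ceiling(protocol$max_time / dt)
  pore_age <- NULL
  rows <- list()
  profiles <- list()
  termination <- "max_time"
  done <- 0L
  while (done < max_steps) {
    chunk <- min(protocol$stride, max_steps - done)
    system <- dpd_step(system, chunk, seed = seed, pull_force = protocol$F)
    done <- done + chunk
    gy <- brush_gyration(system)
    prof <- order_profile(system, profile_bin)
    com <- brush_com_x(system)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      time = system$state$time - t0,
      rg = gy$Rg, delta = gy$delta,
      p2_membrane = mean(prof$p2[prof$occupied]),
      temperature = kinetic_temperature(system),
      contacts = brush_head_contacts(system),
      brush_com_x = com)
    profiles[[length(profiles) + 1L]] <- prof
    occ <- tail_occupancy(system, protocol$pore_cell)
    if (is.null(pore_age)) pore_age <- integer(length(occ))
    pore_age <- ifelse(occ, 0L, pore_age + 1L)
    if (any(pore_age >= protocol$pore_persist)) {
      termination <- "pore"
      break
    }
    if (com >= Lx - protocol$edge_margin) {
      termination <- "edge"
      break
    }
  }
  series <- dplyr::bind_rows(rows)
  landmarks <- tryCatch(
    detect_landmarks(series$time, series$rg, smoothing_window),
    error = function(e) structure(list(T1 = NA_real_, T2 = NA_real_,
                                       Te = max(series$time)),
                                  class = "landmark_times"))
  structure(list(series = series, profiles = profiles, landmarks = landmarks,
                 termination = termination, protocol = protocol,
                 system = system),
            class = "dpd_pull")
}

#' @export
print.dpd_pull <- function(x, ...) {
  cat("Constant-force pull: F =", x$protocol$F, ", aBM =", x$protocol$abm, "\n")
  cat("  terminated by", x$termination, "after",
      round(max(x$series$time), 2), "tau (", nrow(x$series), "samples )\n")
  print(x$landmarks)
  invisible(x)
}

# post-transient time average over [frac * Te, Te]
window_mean <- function(series, col, frac = 0.2) {
  te <- max(series$time)
  w <- series$time >= frac * te
  mean(series[[col]][w])
}

#' Sweep the pulling force
#'
#' Runs one independent pulling experiment per force value (fresh build via
#' `system_factory`, fresh equilibration, documented derived seeds) and
#' aggregates post-transient time averages of the brush Rg and shape factor
#' and the membrane-mean order parameter over the window `[0.2 Te, Te]`.
#' Per-force failures are recorded and the sweep continues.
#'
#' @param F_values Numeric vector of per-bead pulling forces (>= 1 value).
#' @param abm Adsorption parameter used for every run.
#' @param system_factory Function `(abm, seed) -> dpd_system` building a
#'   fresh system.
#' @param seed Master seed. With `paired_seeds = TRUE` (default) every force
#'   uses the same build and noise seed, so runs differ only through F (a
#'   paired comparison); otherwise run i uses `seed + i`.
#' @param equilibration_steps,max_time,stride Protocol settings shared by all
#'   runs.
#' @param window Fraction of Te excluded as transient from the averages.
#' @param paired_seeds Share one seed across forces (paired design).
#' @return A `dpd_sweep`: tibble with one row per force (`F`, `rg`, `delta`,
#'   `p2_membrane`, landmark times, termination, error flag) plus the run
#'   list.
#' @export
run_sweep <- function(F_values, abm, system_factory, seed = 0,
                      equilibration_steps = 2000L, max_time = 30,
                      stride = 100L, window = 0.2, paired_seeds = TRUE) {
  stopifnot(length(F_values) >= 1)
  runs <- vector("list", length(F_values))
  rows <- vector("list", length(F_values))
  for (i in seq_along(F_values)) {
    Fi <- F_values[i]
    seed_i <- if (paired_seeds) seed else seed + i
    rows[[i]] <- tryCatch({
      sys <- system_factory(abm = abm, seed = seed_i)
      sys <- equilibrate(sys, equilibration_steps, seed = seed_i)
      proto <- pull_protocol(Fi, abm = abm,
                             equilibration_steps = equilibration_steps,
                             max_time = max_time, stride = stride)
      pull <- run_pull(sys, proto, seed = seed_i)
      runs[[i]] <- pull
      tibble::tibble(
        F = Fi, seed = seed_i,
        rg = window_mean(pull$series, "rg", window),
        delta = window_mean(pull$series, "delta", window),
        p2_membrane = window_mean(pull$series, "p2_membrane", window),
        T1 = pull$landmarks$T1, T2 = pull$landmarks$T2,
        Te = pull$landmarks$Te,
        n_samples = sum(pull$series$time >= window * max(pull$series$time)),
        window_start = window * max(pull$series$time),
        termination = pull$termination, failed = FALSE, error = NA_character_)
    }, error = function(e) {
      tibble::tibble(F = Fi, seed = seed_i, rg = NA_real_, delta = NA_real_,
                     p2_membrane = NA_real_, T1 = NA_real_, T2 = NA_real_,
                     Te = NA_real_, n_samples = 0L, window_start = NA_real_,
                     termination = NA_character_, failed = TRUE,
                     error = conditionMessage(e))
    })
  }
  structure(list(results = dplyr::bind_rows(rows), runs = runs, abm = abm,
                 seed = seed),
            class = "dpd_sweep")
}

#' @export
print.dpd_sweep <- function(x, ...) {
  cat("Force sweep at aBM =", x$abm, "\n")
  print(x$results)
  invisible(x)
}

#' Preset study systems
#'
#' `"full"` is the full-scale study setup: 400 x 30 x 20 rc box at rho = 3
#' (720,000 beads), H3T4 lipids at one per rc^2 of leaflet area, and an
#' NM = 100, nS = 98, NS = 10 bottlebrush. `"small"` is the desk-scale preset
#' used for testing: 60 x 20 x 16 rc box with an NM = 30, nS = 28, NS = 5
#' brush at the same densities.
#'
#' @param preset `"small"` or `"full"`.
#' @param abm Adsorption parameter for the interaction table.
#' @param seed Build seed (jitter, tilts, solvent, velocities).
#' @param with_brush Include the bottlebrush.
#' @param with_solvent Fill with solvent to rho V.
#' @param params A [dpd_params()].
#' @return A `dpd_system`.
#' @export
preset_system <- function(preset = c("small", "full"), abm = -5, seed = 1,
                          with_brush = TRUE, with_solvent = TRUE,
                          params = dpd_params()) {
  preset <- match.arg(preset)
  if (preset == "full") {
    box <- box_spec(400, 30, 20, rho = 3)
    bspec <- brush_spec(100, 98, 10)
  } else {
    box <- box_spec(60, 20, 16, rho = 3)
    bspec <- brush_spec(30, 28, 5)
  }
  membrane <- build_bilayer(box, lipid_spec(), seed = seed)
  brush <- if (with_brush)
    build_bottlebrush(bspec, row_length = max(4L, floor(0.16 * box$Lx)),
                      layout = "coil", seed = seed + 37L)
  else NULL
  assemble_system(membrane = membrane, brush = brush, solvent = with_solvent,
                  table = interaction_table(abm = abm), box = box,
                  params = params, seed = seed)
}
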
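# Topology builders: bead-spring fragments for the bottlebrush, the supported
# bilayer and the solvent bath, plus system assembly.

new_fragment <- function(positions, species, bonds, angles, fixed = integer(),
                         mol_id, mol_type, tails = NULL, leaflet = NULL) {
  structure(list(positions = positions, species = species, bonds = bonds,
                 angles = angles, fixed = fixed, mol_id = mol_id,
                 mol_type = mol_type, tails = tails, leaflet = leaflet),
            class = "dpd_fragment")
}

empty_bonds <- function() matrix(numeric(), 0, 4,
                                 dimnames = list(NULL, c("i", "j", "ks", "rs")))
empty_angles <- function() matrix(numeric(), 0, 5,
                                  dimnames = list(NULL, c("i", "j", "k", "ktheta", "theta0")))

# grow one self-avoiding persistent random walk inside an axis-aligned slab;
# `existing` rows are beads the walk must stay 0.1 rc away from
grow_walk <- function(n, start, rs, lims, existing, persistence = 0.85,
                      min_sep = 0.1, max_tries = 40L) {
  pos <- matrix(0, n, 3)
  pos[1, ] <- start
  dir <- rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  for (k in seq_len(n - 1) + 1L) {
    placed <- rbind(existing, pos[seq_len(k - 1), , drop = FALSE])
    for (try in seq_len(max_tries)) {
      d <- persistence * dir + rnorm(3)
      d <- d / sqrt(sum(d^2))
      cand <- pos[k - 1, ] + rs * d
      # reflect components that leave the slab
      for (ax in 1:3) {
        if (cand[ax] < lims[1, ax] || cand[ax] > lims[2, ax]) {
          d[ax] <- -d[ax]
          cand[ax] <- pos[k - 1, ax] + rs * d[ax]
        }
      }
      dd <- sqrt(min(rowSums(sweep(placed, 2, cand)^2)))
      if (dd >= min_sep) break
    }
    pos[k, ] <- cand
    dir <- d
  }
  pos
}

#' Build a bottlebrush polymer fragment
#'
#' Two initial layouts are available. `"serpentine"` lays the backbone out as
#' a deterministic serpentine in the x-y plane (rows of `row_length` beads,
#' successive bonds at the equilibrium length `rs`) with one straight
#' sidechain along +z grafted to every backbone bead except the two chain
#' ends. `"coil"` grows the backbone and sidechains as self-avoiding
#' persistent random walks inside a compact slab (lateral extent
#' `row_length * rs`), emulating a relaxed brush conformation so that little
#' equilibration is needed before pulling. Harmonic angles with equilibrium
#' angle pi are laid along the backbone and along each sidechain. All initial
#' bead separations are at least 0.1 rc and all bonds start at `rs`.
#'
#' @param spec A [brush_spec()].
#' @param bond List with `ks` and `rs` for all brush bonds (defaults 200, 0.5).
#' @param angle List with `ktheta` and `theta0` (defaults 4.5, pi).
#' @param origin Numeric length-3; position of the first backbone bead
#'   (serpentine) or slab corner (coil).
#' @param row_length Backbone beads per serpentine row; for the coil layout,
#'   `row_length * rs` is the lateral slab extent.
#' @param layout `"serpentine"` (deterministic) or `"coil"` (random,
#'   seed-controlled).
#' @param seed Optional seed for the coil layout.
#' @return A `dpd_fragment` with `NM + nS * NS` beads.
#' @export
build_bottlebrush <- function(spec, bond = list(ks = 200, rs = 0.5),
                              angle = list(ktheta = 4.5, theta0 = pi),
                              origin = c(0, 0, 0), row_length = 20L,
                              layout = c("serpentine", "coil"), seed = NULL) {
  stopifnot(inherits(spec, "brush_spec"))
  layout <- match.arg(layout)
  if (!is.null(seed)) set.seed(seed)
  NM <- spec$NM; nS <- spec$nS; NS <- spec$NS
  rs <- bond$rs
  n <- NM + nS * NS
  pos <- matrix(0, n, 3)
  side_first <- integer(NM) # 0 = none

  if (layout == "serpentine") {
    # backbone serpentine
    for (b in seq_len(NM)) {
      row <- (b - 1) %/% row_length
      col <- (b - 1) %% row_length
      if (row %% 2 == 1) col <- row_length - 1 - col
      pos[b, ] <- origin + c(col * rs, row * rs, 0)
    }
    # sidechains: one per interior backbone bead, straight up
    idx <- NM
    for (b in 2:(NM - 1)) {
      side_first[b] <- idx + 1L
      for (k in seq_len(NS)) {
        idx <- idx + 1L
        pos[idx, ] <- pos[b, ] + c(0, 0, k * rs)
      }
    }
  } else {
    # compact coil: backbone walk in a slab, then sidechain walks
    wx <- max(3, row_length * rs)
    zspan <- max(2, NS * rs + 1)
    lims <- rbind(origin, origin + c(wx, wx, zspan))
    start <- origin + c(wx / 2, wx / 2, zspan / 2)
    pos[seq_len(NM), ] <- grow_walk(NM, start, rs, lims,
                                    matrix(numeric(), 0, 3))
    idx <- NM
    for (b in 2:(NM - 1)) {
      side_first[b] <- idx + 1L
      side <- grow_walk(NS + 1L, pos[b, ], rs, lims,
                        pos[seq_len(idx), , drop = FALSE])
      pos[idx + seq_len(NS), ] <- side[-1, , drop = FALSE]
      idx <- idx + NS
    }
  }

  bonds <- vector("list", NM - 1 + nS * NS)
  bi <- 0L
  for (b in seq_len(NM - 1)) {
    bi <- bi + 1L
    bonds[[bi]] <- c(b, b + 1, bond$ks, rs)
  }
  for (b in 2:(NM - 1)) {
    f <- side_first[b]
    bi <- bi + 1L
    bonds[[bi]] <- c(b, f, bond$ks, rs) # graft bond
    if (NS > 1) {
      for (k in seq_len(NS - 1)) {
        bi <- bi + 1L
        bonds[[bi]] <- c(f + k - 1, f + k, bond$ks, rs)
      }
    }
  }
  bonds <- do.call(rbind, bonds[seq_len(bi)])
  colnames(bonds) <- c("i", "j", "ks", "rs")

  angles <- list()
  if (NM >= 3)
    for (b in seq_len(NM - 2))
      angles[[length(angles) + 1L]] <- c(b, b + 1, b + 2, angle$ktheta, angle$theta0)
  if (NS >= 3)
    for (b in 2:(NM - 1)) {
      f <- side_first[b]
      for (k in seq_len(NS - 2))
        angles[[length(angles) + 1L]] <-
          c(f + k - 1, f + k, f + k + 1, angle$ktheta, angle$theta0)
    }
  angles <- if (length(angles)) do.call(rbind, angles) else empty_angles()
  colnames(angles) <- c("i", "j", "k", "ktheta", "theta0")

  new_fragment(pos, rep(c(SPECIES[["BRUSH_BACKBONE"]], SPECIES[["BRUSH_SIDE"]]),
                        c(NM, nS * NS)),
               bonds, angles, integer(), rep(1L, n), "brush")
}

# draw a unit vector in a cone about +z: cos(theta) uniform on [cmin, 1]
cone_direction <- function(cmin) {
  ct <- runif(1, cmin, 1)
  st <- sqrt(1 - ct^2)
  phi <- runif(1, 0, 2 * pi)
  c(st * cos(phi), st * sin(phi), ct)
}

#' Build a supported bilayer fragment
#'
#' Places two leaflets of lipids on a jittered square lattice spanning the x-y
#' plane, tails pointing inward. Head chains are normal to the membrane; each
#' tail is laid straight along a direction drawn uniformly from a cone about
#' the leaflet normal (`tilt_cos_min` is the cosine of the cone half-angle),
#' which is what "random arrangement" means here: the freshly built membrane
#' has a disordered tail tilt with expected P2 order parameter
#' `(tilt_cos_min + tilt_cos_min^2) / 2` (0.25 at the default). The two head
#' beads of every lower-leaflet lipid nearest the substrate plane are fixed.
#'
#' @param box A [box_spec()].
#' @param lipid A [lipid_spec()].
#' @param area_per_lipid Leaflet area per lipid in rc^2.
#' @param jitter Uniform in-plane lattice jitter amplitude (rc).
#' @param tilt_cos_min Cosine of the maximum initial tail tilt; 1 builds a
#'   perfectly aligned membrane.
#' @param z0 Height of the substrate-fixed head beads (rc).
#' @param bond,angle Bonded-parameter lists; defaults ks = 120, rs = 0.7,
#'   ktheta = 6, with equilibrium angle pi for pure head/tail triples and
#'   2*pi/3 for triples spanning the head-tail connective point.
#' @param seed Optional integer seed for the jitter and tilt draws.
#' @return A `dpd_fragment`; per-lipid bead count is `n_head + 2 * n_tail`.
#' @export
build_bilayer <- function(box, lipid = lipid_spec(), area_per_lipid = 1,
                          jitter = 0.1, tilt_cos_min = (sqrt(3) - 1) / 2,
                          z0 = 0.5,
                          bond = list(ks = 120, rs = 0.7),
                          angle = list(ktheta = 6, theta0_straight = pi,
                                       theta0_junction = 2 * pi / 3),
                          seed = NULL) {
  stopifnot(inherits(box, "box_spec"), inherits(lipid, "lipid_spec"),
            area_per_lipid > 0)
  if (!is.null(seed)) set.seed(seed)
  s <- sqrt(area_per_lipid)
  nx <- round(box$Lx / s); ny <- round(box$Ly / s)
  if (nx < 1 || ny < 1) stop("box too small for a single lipid")
  sx <- box$Lx / nx; sy <- box$Ly / ny
  if (abs(sx * sy / area_per_lipid - 1) > 0.25)
    stop("area_per_lipid inconsistent with the box x-y dimensions")

  nh <- lipid$n_head; nt <- lipid$n_tail
  rs <- bond$rs
  per_lipid <- nh + 2L * nt
  n_leaf <- nx * ny
  n_lipids <- 2L * n_leaf
  # z separation between the outermost head beads of the two leaflets
  ct_mean <- (1 + tilt_cos_min) / 2
  zsep <- 2 * ((nh - 1) * rs + nt * rs * ct_mean) + 0.4
  if (z0 + zsep > box$Lz - 1)
    stop("box too short in z for the bilayer (need ", round(z0 + zsep + 1, 2),
         " rc)")

  n <- n_lipids * per_lipid
  pos <- matrix(0, n, 3)
  species <- integer(n)
  fixed <- integer(0)
  bonds <- vector("list", n_lipids * (per_lipid - 1))
  angles <- vector("list", n_lipids * (nh - 2 + 2 * (2 + nt - 2)))
  tails <- matrix(0L, n_lipids * 2L, 4,
                  dimnames = list(NULL, c("mol", "first", "last", "leaflet")))
  leaflet <- integer(n_lipids)
  mol_id <- integer(n)
  bi <- 0L; ai <- 0L; ti <- 0L

  mol <- 0L
  off <- 0L
  for (leaf in 1:2) {
    zdir <- if (leaf == 1) 1 else -1        # tails point up (lower) / down (upper)
    zhead <- if (leaf == 1) z0 else z0 + zsep # outermost head bead height
    for (ix in seq_len(nx)) {
      for (iy in seq_len(ny)) {
        mol <- mol + 1L
        leaflet[mol] <- leaf
        x <- (ix - 0.5) * sx + runif(1, -jitter, jitter)
        y <- (iy - 0.5) * sy + runif(1, -jitter, jitter)
        h <- off + seq_len(nh)
        for (k in seq_len(nh))
          pos[off + k, ] <- c(x, y, zhead + zdir * (k - 1) * rs)
        species[h] <- SPECIES[["HEAD"]]
        if (leaf == 1) fixed <- c(fixed, off + 1L, off + 2L)
        anchor <- pos[off + nh, ]
        toff <- off + nh
        for (tchain in 1:2) {
          d <- cone_direction(tilt_cos_min)
          if (tchain == 2) {
            tries <- 0
            while (sqrt(sum((d - d1)^2)) < 0.2 && tries < 50) {
              d <- cone_direction(tilt_cos_min)
              tries <- tries + 1
            }
          } else d1 <- d
          d <- d * c(1, 1, zdir)
          for (k in seq_len(nt))
            pos[toff + k, ] <- anchor + k * rs * d
          species[toff + seq_len(nt)] <- SPECIES[["TAIL"]]
          # bonds: junction + tail internal
          bi <- bi + 1L; bonds[[bi]] <- c(off + nh, toff + 1, bond$ks, rs)
          for (k in seq_len(nt - 1)) {
            bi <- bi + 1L
            bonds[[bi]] <- c(toff + k, toff + k + 1, bond$ks, rs)
          }
          # angles spanning the connective point (equilibrium 2*pi/3)
          ai <- ai + 1L
          angles[[ai]] <- c(off + nh - 1, off + nh, toff + 1,
                            angle$ktheta, angle$theta0_junction)
          ai <- ai + 1L
          angles[[ai]] <- c(off + nh, toff + 1, toff + 2,
                            angle$ktheta, angle$theta0_junction)
          # pure tail triples
          for (k in seq_len(nt - 2)) {
            ai <- ai + 1L
            angles[[ai]] <- c(toff + k, toff + k + 1, toff + k + 2,
                              angle$ktheta, angle$theta0_straight)
          }
          ti <- ti + 1L
          tails[ti, ] <- c(mol, toff + 1L, toff + nt, leaf)
          toff <- toff + nt
        }
        # head bonds and pure head triples
        for (k in seq_len(nh - 1)) {
          bi <- bi + 1L
          bonds[[bi]] <- c(off + k, off + k + 1, bond$ks, rs)
        }
        for (k in seq_len(nh - 2)) {
          ai <- ai + 1L
          angles[[ai]] <- c(off + k, off + k + 1, off + k + 2,
                            angle$ktheta, angle$theta0_straight)
        }
        mol_id[off + seq_len(per_lipid)] <- mol
        off <- off + per_lipid
      }
    }
  }
  bonds <- do.call(rbind, bonds[seq_len(bi)])
  colnames(bonds) <- c("i", "j", "ks", "rs")
  angles <- do.call(rbind, angles[seq_len(ai)])
  colnames(angles) <- c("i", "j", "k", "ktheta", "theta0")
  # wrap x-y into the box
  pos[, 1] <- pos[, 1] %% box$Lx
  pos[, 2] <- pos[, 2] %% box$Ly

  new_fragment(pos, species, bonds, angles, fixed, mol_id,
               rep("lipid", n_lipids), tails = tails, leaflet = leaflet)
}

#' Fill the box with solvent beads
#'
#' Adds SOLVENT beads uniformly at random so the total bead count reaches
#' `round(rho * V)`, excluding a shell of radius `exclusion` around every
#' occupied position.
#'
#' @param box A [box_spec()].
#' @param occupied Matrix of occupied positions (may have zero rows).
#' @param exclusion Exclusion-shell radius around occupied beads (rc).
#' @param seed Optional seed.
#' @param max_tries Retry budget for the rejection sampler.
#' @return Matrix of solvent positions.
#' @export
fill_solvent <- function(box, occupied = matrix(numeric(), 0, 3),
                         exclusion = 0.5, seed = NULL, max_tries = 50L) {
  stopifnot(inherits(box, "box_spec"))
  if (!is.null(seed)) set.seed(seed)
  target <- round(box$rho * box$Lx * box$Ly * box$Lz)
  need <- target - nrow(occupied)
  if (need < 0)
    stop("occupied bead count exceeds rho * V (", nrow(occupied), " > ",
         target, ")")
  if (need == 0) return(matrix(numeric(), 0, 3))
  L <- box_lengths(box)
  got <- matrix(numeric(), 0, 3)
  for (try in seq_len(max_tries)) {
    m <- ceiling(1.3 * (need - nrow(got)))
    cand <- cbind(runif(m, 0, L[1]), runif(m, 0, L[2]), runif(m, 0, L[3]))
    ok <- cpp_free_points(cand, occupied, L, exclusion)
    got <- rbind(got, cand[ok, , drop = FALSE])
    if (nrow(got) >= need) return(got[seq_len(need), , drop = FALSE])
  }
  stop("solvent placement failed: could not place ", need,
       " beads outside the exclusion shells")
}

shift_fragment <- function(frag, offset) {
  n0 <- offset
  frag$bonds[, 1:2] <- frag$bonds[, 1:2] + n0
  if (nrow(frag$angles)) frag$angles[, 1:3] <- frag$angles[, 1:3] + n0
  frag$fixed <- frag$fixed + n0
  if (!is.null(frag$tails)) frag$tails[, 2:3] <- frag$tails[, 2:3] + n0
  frag
}

#' Assemble the full simulation system
#'
#' Merges the membrane and brush fragments, places the brush just above the
#' upper leaflet at the low-x end of the box (its center of mass must fall in
#' the first 10 percent of the x-range), fills the remaining volume with
#' solvent, and draws initial velocities from a zero-mean Gaussian at
#' variance kBT/m with the net momentum of the free beads removed. Fixed
#' (substrate) beads start and stay at zero velocity.
#'
#' @param membrane A bilayer `dpd_fragment` (or NULL).
#' @param brush A bottlebrush `dpd_fragment` (or NULL).
#' @param solvent TRUE to fill to `rho * V`, FALSE for none, or a positions
#'   matrix to use directly.
#' @param table An [interaction_table()].
#' @param box A [box_spec()].
#' @param params A [dpd_params()].
#' @param seed Optional master seed (solvent placement and velocity draws use
#'   streams derived from it).
#' @param brush_gap Vertical gap between the topmost membrane bead and the
#'   brush backbone plane (rc).
#' @return A `dpd_system`: state (positions, velocities, images, box, clock),
#'   topology, interaction table and parameters.
#' @export
assemble_system <- function(membrane = NULL, brush = NULL, solvent = TRUE,
                            table = interaction_table(), box,
                            params = dpd_params(), seed = NULL,
                            brush_gap = 0.8) {
  validate_interaction_table(table)
  stopifnot(inherits(box, "box_spec"))
  if (!is.null(seed)) set.seed(seed)

  frags <- list()
  if (!is.null(membrane)) frags$membrane <- membrane
  if (!is.null(brush)) {
    if (!is.null(membrane)) {
      ztop <- max(membrane$positions[membrane$species == SPECIES[["HEAD"]], 3])
    } else ztop <- 0
    p <- brush$positions
    p[, 1] <- p[, 1] - min(p[, 1]) + 0.5
    yspan <- diff(range(p[, 2]))
    p[, 2] <- p[, 2] - min(p[, 2]) + (box$Ly - yspan) / 2
    p[, 3] <- p[, 3] - min(p[, 3]) + ztop + brush_gap
    if (max(p[, 3]) > box$Lz - 0.5)
      stop("box too short in z to place the brush above the membrane")
    comx <- mean(p[, 1])
    if (comx >= 0.1 * box$Lx)
      stop("brush placement violates the low-x rule: center of mass at x = ",
           round(comx, 2), " >= 0.1 * Lx; use a shorter serpentine row")
    brush$positions <- p
    frags$brush <- brush
  }
  if (length(frags) == 0 && isFALSE(solvent))
    stop("nothing to assemble")

  pos <- do.call(rbind, lapply(frags, function(f) f$positions))
  if (is.null(pos)) pos <- matrix(numeric(), 0, 3)
  species <- unlist(lapply(frags, function(f) f$species), use.names = FALSE)
  bonds <- empty_bonds(); angles <- empty_angles()
  fixed <- integer(); tails <- NULL; leaflet <- NULL
  mol_id <- integer(); mol_type <- character()
  brush_range <- NULL
  off <- 0L
  for (nm in names(frags)) {
    f <- shift_fragment(frags[[nm]], off)
    bonds <- rbind(bonds, f$bonds)
    angles <- rbind(angles, f$angles)
    fixed <- c(fixed, f$fixed)
    if (!is.null(f$tails)) tails <- rbind(tails, f$tails)
    if (!is.null(f$leaflet)) leaflet <- c(leaflet, f$leaflet)
    mol_id <- c(mol_id, f$mol_id + length(mol_type))
    mol_type <- c(mol_type, f$mol_type)
    if (nm == "brush") brush_range <- off + seq_len(nrow(f$positions))
    off <- off + nrow(frags[[nm]]$positions)
  }

  if (isTRUE(solvent)) {
    solv <- fill_solvent(box, pos, seed = if (is.null(seed)) NULL else seed + 1000003L)
  } else if (is.matrix(solvent)) {
    solv <- solvent
  } else solv <- matrix(numeric(), 0, 3)
  if (nrow(solv)) {
    pos <- rbind(pos, solv)
    species <- c(species, rep(SPECIES[["SOLVENT"]], nrow(solv)))
    mol_id <- c(mol_id, length(mol_type) + seq_len(nrow(solv)))
    mol_type <- c(mol_type, rep("solvent", nrow(solv)))
  }

  n <- nrow(pos)
  if (!is.null(seed)) set.seed(seed + 2000003L)
  vel <- matrix(rnorm(3 * n, sd = sqrt(params$kBT)), n, 3)
  free <- setdiff(seq_len(n), fixed)
  vel[fixed, ] <- 0
  vel[free, ] <- sweep(vel[free, , drop = FALSE], 2,
                       colMeans(vel[free, , drop = FALSE]))

  topology <- structure(list(species = as.integer(species), bonds = bonds,
                             angles = angles, fixed = sort(fixed),
                             mol_id = mol_id, mol_type = mol_type,
                             tails = tails, leaflet = leaflet,
                             brush = brush_range),
                        class = "dpd_topology")
  state <- list(positions = pos, velocities = vel,
                images = matrix(0L, n, 3), box = box_lengths(box),
                rho = box$rho, step = 0L, time = 0, forces = NULL)
  structure(list(state = state, topology = topology, table = table,
                 params = params, seed = seed),
            class = "dpd_system")
}

#' Construct a system from raw arrays
#'
#' Low-level constructor used by the builders, the fixtures and tests:
#' assembles a `dpd_system` directly from positions and topology pieces.
#' Velocities default to zero; positions are wrapped into the box.
#'
#' @param positions N x 3 matrix.
#' @param box Length-3 box edges (rc) or a [box_spec()].
#' @param species Integer codes 1-5 (see [species_levels()]); defaults to
#'   SOLVENT for all beads.
#' @param velocities N x 3 matrix or NULL for zero.
#' @param bonds,angles Bond/angle matrices (`i j ks rs` / `i j k ktheta
#'   theta0`).
#' @param fixed Indices of immobile beads.
#' @param brush Indices forming the brush molecule (pulling selection), or
#'   NULL.
#' @param tails Optional lipid-tail index matrix (`mol first last leaflet`)
#'   for the order-profile machinery.
#' @param table An [interaction_table()].
#' @param params A [dpd_params()].
#' @return A `dpd_system`.
#' @export
dpd_system <- function(positions, box, species = NULL, velocities = NULL,
                       bonds = NULL, angles = NULL, fixed = integer(),
                       brush = NULL, tails = NULL, table = interaction_table(),
                       params = dpd_params()) {
  if (inherits(box, "box_spec")) box <- box_lengths(box)
  positions <- rbind(positions)
  n <- nrow(positions)
  for (k in 1:3) positions[, k] <- positions[, k] %% box[k]
  if (is.null(species)) species <- rep(SPECIES[["SOLVENT"]], n)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  if (is.null(bonds)) bonds <- empty_bonds()
  if (is.null(angles)) angles <- empty_angles()
  validate_interaction_table(table)
  topology <- structure(list(species = as.integer(species), bonds = bonds,
                             angles = angles, fixed = as.integer(fixed),
                             mol_id = seq_len(n), mol_type = rep("raw", n),
                             tails = tails, leaflet = NULL,
                             brush = brush),
                        class = "dpd_topology")
  state <- list(positions = positions, velocities = velocities,
                images = matrix(0L, n, 3), box = box, rho = NA_real_,
                step = 0L, time = 0, forces = NULL)
  structure(list(state = state, topology = topology, table = table,
                 params = params, seed = NULL),
            class = "dpd_system")
}

#' @export
print.dpd_system <- function(x, ...) {
  tp <- x$topology
  cat("DPD system:", nrow(x$state$positions), "beads in box",
      paste(x$state$box, collapse = " x "), "rc\n")
  cat("  species:", paste(sprintf("%s=%d", species_levels(),
                                  tabulate(tp$species, 5)), collapse = ", "), "\n")
  cat("  bonds:", nrow(tp$bonds), " angles:", nrow(tp$angles),
      " fixed beads:", length(tp$fixed), "\n")
  cat("  t =", x$state$time, "tau (step", x$state$step, ")\n")
  invisible(x)
}

#' Number of beads in a system
#' @param system A `dpd_system`.
#' @return Integer bead count.
#' @export
n_beads <- function(system) nrow(system$state$positions)

#' Unwrapped bead coordinates
#'
#' Adds the accumulated periodic image counts back onto the wrapped
#' coordinates, giving continuous trajectories across box faces.
#'
#' @param system A `dpd_system`.
#' @return N x 3 matrix of unwrapped positions.
#' @export
unwrapped_positions <- function(system) {
  st <- system$state
  st$positions + st$images %*% diag(st$box)
}

#' Audit initial bond lengths
#'
#' Checks every bond in the current configuration against its equilibrium
#' length: all must lie between half and twice the equilibrium length rs.
#'
#' @param system A `dpd_system`.
#' @return Invisibly TRUE; errors otherwise.
#' @export
audit_topology <- function(system) {
  b <- system$topology$bonds
  if (nrow(b) == 0) return(invisible(TRUE))
  p <- system$state$positions
  L <- system$state$box
  d <- p[b[, 1], , drop = FALSE] - p[b[, 2], , drop = FALSE]
  for (k in 1:3) d[, k] <- d[, k] - L[k] * round(d[, k] / L[k])
  len <- sqrt(rowSums(d^2))
  bad <- len < 0.5 * b[, "rs"] | len > 2 * b[, "rs"]
  if (any(bad))
    stop(sum(bad), " bonds outside [0.5 rs, 2 rs] in the initial configuration")
  invisible(TRUE)
}
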
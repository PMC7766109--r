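# Readers/writers shared by all modules: XYZ and LAMMPS-dump trajectories,
# LAMMPS-style data files, CSV time series, YAML configuration and the JSON
# run manifest. All text output is in reduced units at 6 decimal places;
# checkpoints keep full precision.

species_labels_of <- function(topology) species_levels()[topology$species]

#' Write a trajectory frame
#'
#' XYZ dialect: bead count line, a comment line carrying the simulation time,
#' then one `label x y z` line per bead. LAMMPS dump dialect: the usual
#' `ITEM: TIMESTEP / NUMBER OF ATOMS / BOX BOUNDS pp pp pp / ATOMS id type
#' x y z ix iy iz` blocks with image flags.
#'
#' @param system A `dpd_system`.
#' @param file Path or connection.
#' @param dialect `"xyz"` or `"lammps_dump"`.
#' @param append Append to an existing trajectory file.
#' @param digits Coordinate precision (decimal places).
#' @return Invisibly `file`.
#' @export
write_trajectory_frame <- function(system, file, dialect = c("xyz", "lammps_dump"),
                                   append = FALSE, digits = 6) {
  dialect <- match.arg(dialect)
  if (dialect == "xyz") write_xyz(system, file, append = append, digits = digits)
  else write_lammps_dump(system, file, append = append, digits = digits)
}

#' @rdname write_trajectory_frame
#' @export
write_xyz <- function(system, file, append = FALSE, digits = 6) {
  st <- system$state
  fmt <- paste0("%s %.", digits, "f %.", digits, "f %.", digits, "f")
  lines <- c(
    as.character(nrow(st$positions)),
    sprintf("t= %g tau, step= %d", st$time, st$step),
    sprintf(fmt, species_labels_of(system$topology),
            st$positions[, 1], st$positions[, 2], st$positions[, 3]))
  con <- base::file(file, open = if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(file)
}

#' @rdname write_trajectory_frame
#' @export
write_lammps_dump <- function(system, file, append = FALSE, digits = 6) {
  st <- system$state
  n <- nrow(st$positions)
  fmt <- paste0("%d %d %.", digits, "f %.", digits, "f %.", digits, "f %d %d %d")
  lines <- c(
    "ITEM: TIMESTEP", as.character(st$step),
    "ITEM: NUMBER OF ATOMS", as.character(n),
    "ITEM: BOX BOUNDS pp pp pp",
    sprintf("0 %.6f", st$box[1]),
    sprintf("0 %.6f", st$box[2]),
    sprintf("0 %.6f", st$box[3]),
    "ITEM: ATOMS id type x y z ix iy iz",
    sprintf(fmt, seq_len(n), system$topology$species,
            st$positions[, 1], st$positions[, 2], st$positions[, 3],
            st$images[, 1], st$images[, 2], st$images[, 3]))
  con <- base::file(file, open = if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(file)
}

#' Read an XYZ trajectory
#'
#' @param file Path to an XYZ file written by [write_xyz()] (possibly
#'   multi-frame).
#' @return List of frames, each a list with `labels`, `positions` and the
#'   comment line.
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    comment <- lines[i + 1L]
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(body, " ", fixed = TRUE)
    labels <- vapply(parts, `[[`, character(1), 1)
    pos <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), n, 3,
                  byrow = TRUE)
    frames[[length(frames) + 1L]] <- list(labels = labels, positions = pos,
                                          comment = comment)
    i <- i + 2L + n
  }
  frames
}

#' Read a LAMMPS-dump trajectory
#'
#' Parses the dump dialect written by [write_lammps_dump()].
#'
#' @param file Path to the dump file.
#' @return List of frames: `step`, `box`, `species`, `positions`, `images`.
#' @export
read_lammps_dump <- function(file) {
  lines <- readLines(file)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    stopifnot(lines[i] == "ITEM: TIMESTEP")
    step <- as.integer(lines[i + 1L])
    n <- as.integer(lines[i + 3L])
    box <- vapply(lines[i + 5:7], function(s)
      as.numeric(strsplit(s, " ")[[1]][2]), numeric(1))
    body <- lines[(i + 9L):(i + 8L + n)]
    m <- matrix(as.numeric(unlist(strsplit(body, " ", fixed = TRUE))), n, 8,
                byrow = TRUE)
    ord <- order(m[, 1])
    m <- m[ord, , drop = FALSE]
    frames[[length(frames) + 1L]] <- list(
      step = step, box = unname(box), species = as.integer(m[, 2]),
      positions = m[, 3:5, drop = FALSE],
      images = matrix(as.integer(m[, 6:8]), n, 3))
    i <- i + 9L + n
  }
  frames
}

#' Export a LAMMPS-style data file
#'
#' Writes the topology and current configuration in the classic data-file
#' layout (header counts, Masses, Atoms with molecule tags, Bonds, Angles) so
#' a system can be cross-checked in external MD tools. Bond and angle types
#' enumerate the distinct (ks, rs) and (ktheta, theta0) combinations; the
#' coefficient tables are listed in comment lines.
#'
#' @param system A `dpd_system`.
#' @param file Output path.
#' @return Invisibly `file`.
#' @export
write_lammps_data <- function(system, file) {
  st <- system$state
  tp <- system$topology
  n <- nrow(st$positions)
  bkey <- paste(tp$bonds[, "ks"], tp$bonds[, "rs"])
  btypes <- unique(bkey)
  akey <- if (nrow(tp$angles)) paste(tp$angles[, "ktheta"], tp$angles[, "theta0"])
          else character()
  atypes <- unique(akey)
  lines <- c(
    "LAMMPS data file generated by brushpull (reduced units)",
    "",
    sprintf("%d atoms", n),
    sprintf("%d bonds", nrow(tp$bonds)),
    sprintf("%d angles", nrow(tp$angles)),
    "5 atom types",
    sprintf("%d bond types", length(btypes)),
    sprintf("%d angle types", length(atypes)),
    "",
    sprintf("0 %.6f xlo xhi", st$box[1]),
    sprintf("0 %.6f ylo yhi", st$box[2]),
    sprintf("0 %.6f zlo zhi", st$box[3]),
    "",
    "Masses",
    "",
    sprintf("%d 1.0  # %s", 1:5, species_levels()),
    "",
    if (length(btypes))
      sprintf("# bond type %d: ks rs = %s", seq_along(btypes), btypes)
    else character(),
    if (length(atypes))
      sprintf("# angle type %d: ktheta theta0 = %s", seq_along(atypes), atypes)
    else character(),
    "",
    "Atoms  # molecular",
    "",
    sprintf("%d %d %d %.6f %.6f %.6f", seq_len(n), tp$mol_id, tp$species,
            st$positions[, 1], st$positions[, 2], st$positions[, 3]))
  if (nrow(tp$bonds)) {
    lines <- c(lines, "", "Bonds", "",
               sprintf("%d %d %d %d", seq_len(nrow(tp$bonds)),
                       match(bkey, btypes), tp$bonds[, "i"], tp$bonds[, "j"]))
  }
  if (nrow(tp$angles)) {
    lines <- c(lines, "", "Angles", "",
               sprintf("%d %d %d %d %d", seq_len(nrow(tp$angles)),
                       match(akey, atypes), tp$angles[, "i"], tp$angles[, "j"],
                       tp$angles[, "k"]))
  }
  writeLines(lines, file)
  invisible(file)
}

#' Write a sampled time series as CSV
#'
#' @param series Tibble of sampled observables (a `dpd_pull$series`, an
#'   [order_profile()], or any data frame).
#' @param file Output path.
#' @return Invisibly `file`.
#' @export
write_series_csv <- function(series, file) {
  utils::write.csv(as.data.frame(series), file, row.names = FALSE)
  invisible(file)
}

#' Checkpoint a system to disk
#'
#' Full-precision binary snapshot of the state, topology, table, parameters
#' and clock (an RDS file; not a text format — intended for restarts within
#' a run, not for archival).
#'
#' @param system A `dpd_system`.
#' @param file Checkpoint path.
#' @return Invisibly `file`.
#' @export
write_checkpoint <- function(system, file) {
  saveRDS(system, file)
  invisible(file)
}

#' @rdname write_checkpoint
#' @param file Checkpoint path.
#' @return The restored `dpd_system`.
#' @export
read_checkpoint <- function(file) readRDS(file)
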
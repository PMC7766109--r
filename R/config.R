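# Configuration and run manifests. Configuration is layered: package defaults
# (the study's parameter set), overlaid by a YAML file, overlaid by explicit
# overrides (e.g. CLI flags). Unknown keys are errors; the assembled set is
# validated (fluctuation-dissipation, topology consistency) before use.

#' Default configuration
#'
#' The full default parameter set of the study: DPD thermostat (gamma = 4.5,
#' sigma = 3.0, kBT = 1, dt = 0.005, lambda = 0.5), H3T4 lipid with membrane
#' bonds ks = 120, rs = 0.7 and bending ktheta = 6, brush NM = 100 / nS = 98 /
#' NS = 10 with bonds ks = 200, rs = 0.5 and bending ktheta = 4.5, the
#' 400 x 30 x 20 box at rho = 3, adsorption abm = -5, and the pulling
#' protocol (force range 0.8-2.4, stride 100).
#'
#' @return Nested named list of configuration sections.
#' @export
default_config <- function() {
  list(
    params = list(gamma = 4.5, sigma = 3.0, kBT = 1, rc = 1, dt = 0.005,
                  lambda = 0.5),
    lipid = list(n_head = 3L, n_tail = 4L,
                 bond_ks = 120, bond_rs = 0.7,
                 angle_ktheta = 6, angle_theta0_straight = pi,
                 angle_theta0_junction = 2 * pi / 3,
                 area_per_lipid = 1, jitter = 0.1,
                 tilt_cos_min = (sqrt(3) - 1) / 2),
    brush = list(NM = 100L, nS = 98L, NS = 10L,
                 bond_ks = 200, bond_rs = 0.5,
                 angle_ktheta = 4.5, angle_theta0 = pi),
    box = list(Lx = 400, Ly = 30, Lz = 20, rho = 3),
    table = list(abm = -5, brush_tail = 50),
    protocol = list(F = 1.7, equilibration_steps = 10000L, max_time = 120,
                    stride = 100L, edge_margin = 5, pore_cell = 2,
                    pore_persist = 5L),
    seed = 1L
  )
}

merge_config <- function(base, extra, path = "") {
  for (key in names(extra)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop("unknown configuration key: ", full)
    if (is.list(base[[key]]) && is.list(extra[[key]])) {
      base[[key]] <- merge_config(base[[key]], extra[[key]], full)
    } else {
      base[[key]] <- extra[[key]]
    }
  }
  base
}

validate_config <- function(cfg) {
  # constructors run all the domain checks
  do.call(dpd_params, cfg$params)
  lipid_spec(cfg$lipid$n_head, cfg$lipid$n_tail)
  brush_spec(cfg$brush$NM, cfg$brush$nS, cfg$brush$NS)
  box_spec(cfg$box$Lx, cfg$box$Ly, cfg$box$Lz, cfg$box$rho)
  validate_interaction_table(interaction_table(cfg$table$abm,
                                               cfg$table$brush_tail))
  invisible(cfg)
}

#' Load a layered configuration
#'
#' Package defaults, overlaid by the YAML file (if any), overlaid by
#' `overrides` (highest precedence, e.g. command-line flags). Unknown keys at
#' any level are rejected by name; the merged configuration is validated
#' (including the fluctuation-dissipation relation).
#'
#' @param path Path to a YAML configuration file, or NULL for defaults only.
#' @param overrides Nested named list overriding file values.
#' @return The merged, validated configuration list.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    file_cfg <- yaml::read_yaml(path)
    if (length(file_cfg)) cfg <- merge_config(cfg, file_cfg)
  }
  if (!is.null(overrides) && length(overrides))
    cfg <- merge_config(cfg, overrides)
  validate_config(cfg)
  cfg
}

#' Write a configuration file
#'
#' @param cfg Configuration list (see [default_config()]).
#' @param path Output YAML path.
#' @return Invisibly `path`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record sufficient to re-run a simulation bit-identically: the full
#' configuration, master seed, package version, and (once the run finished)
#' the termination reason and output file inventory.
#'
#' @param path Output JSON path.
#' @param config Configuration list used for the run.
#' @param seed Master seed.
#' @param termination Termination reason (NA while the run is in progress).
#' @param files Character vector of output files produced.
#' @return Invisibly `path`.
#' @export
write_manifest <- function(path, config, seed,
                           termination = NA_character_, files = character()) {
  manifest <- list(
    package = "brushpull",
    version = as.character(utils::packageVersion("brushpull")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    termination = termination,
    files = files)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
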
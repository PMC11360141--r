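#' Contact-energy table over the four lattice types
#'
#' Builds the symmetric contact-coefficient matrix J indexed by
#' (medium, substrate, leader, follower). Leader and follower cells share a
#' single cell-cell coefficient; cell-medium and cell-substrate coefficients
#' control how strongly cells round up against medium and wet the substrate.
#' Same-type contacts between voxels of *different* cells of equal type use
#' the same cell-cell coefficient; contacts within one cell carry no energy.
#'
#' @param cell_cell contact coefficient between any two cells.
#' @param cell_medium contact coefficient between a cell and medium.
#' @param cell_substrate contact coefficient between a cell and the substrate.
#' @param medium_substrate coefficient between medium and the substrate plane.
#' @return a 4x4 symmetric numeric matrix with dimnames
#'   `c("medium", "substrate", "leader", "follower")`.
#' @export
contact_energy_table <- function(cell_cell = 4, cell_medium = 4,
                                 cell_substrate = 3, medium_substrate = 0) {
  types <- c("medium", "substrate", "leader", "follower")
  J <- matrix(0, 4, 4, dimnames = list(types, types))
  J["medium", "substrate"] <- J["substrate", "medium"] <- medium_substrate
  for (cell in c("leader", "follower")) {
    J[cell, "medium"] <- J["medium", cell] <- cell_medium
    J[cell, "substrate"] <- J["substrate", cell] <- cell_substrate
  }
  J["leader", "leader"] <- J["follower", "follower"] <- cell_cell
  J["leader", "follower"] <- J["follower", "leader"] <- cell_cell
  J
}

#' Simulation configuration
#'
#' Collects every model parameter of the Cellular-Potts mesendoderm model.
#' The shipped defaults are the calibrated baseline parameterization: they
#' satisfy the calibration gates checked by [calibration_gates()] (cohesive,
#' non-fragmenting explant with persistent forward migration at a speed of
#' order 100 um/h).
#'
#' Units: lengths are in voxels (1 voxel = `microns_per_voxel` um = 6 um,
#' so a 5-voxel cell edge is 30 um), time in Monte-Carlo steps
#' (1 MCS = `seconds_per_mcs` s = 5 s), energies in the dimensionless
#' effective-energy scale set by `temperature`.
#'
#' @param contact_energy 4x4 symmetric contact matrix, see
#'   [contact_energy_table()].
#' @param lambda_volume strength of the quadratic volume constraint.
#' @param v_target target cell volume in voxels (5x5x5 cube = 125).
#' @param temperature Cellular-Potts fluctuation amplitude (> 0).
#' @param lambda_tissue stiffness of cell-cell elastic links.
#' @param lambda_lamellipodia tension of leader lamellipodium links
#'   (energy is linear in length, so this is the force magnitude).
#' @param lambda_follower_substrate stiffness of follower-substrate links.
#' @param zeta_lamellipodia,zeta_substrate,zeta_tissue Poisson rates per
#'   timestep for lamellipodium cycling, follower-substrate re-anchoring and
#'   cell-cell link break/reform turnover. The per-step firing probability is
#'   `1 - exp(-zeta)`.
#' @param chi_lamellipodia distance (voxels) beyond the selected free-edge
#'   voxel at which a new lamellipodium anchor is placed.
#' @param kappa cohesotaxis bias in `[-6, 6]`; -6 is no bias, +6 maximal.
#' @param link_target_length rest length of cell-cell links (voxels).
#' @param substrate_link_target_length rest length of follower-substrate
#'   links; defaults to the height of a bottom-layer centroid above the
#'   substrate plane so a resting follower carries no elastic energy.
#' @param max_reformed_neighbors cap on cell-cell links a cell may hold after
#'   intercalation reformation (sane range 4-5).
#' @param mcs_per_sample sampling interval for trajectories (200 MCS = 17 min).
#' @param seconds_per_mcs seconds of real time per MCS.
#' @param microns_per_voxel microns per lattice voxel.
#' @param bias_toward `"far"` selects protrusion sites with the largest
#'   cumulative distance to cell-cell borders (away from contacts);
#'   `"near"` is the opposite reading, kept as a switch.
#' @param leader_rows `"bottom"` assigns the 8 bottom-layer leading-edge
#'   cells as leaders; `"full_face"` assigns the whole 16-cell leading face.
#' @param connectivity_constraint reject voxel-copy attempts that would split
#'   the losing cell's voxels within the local 26-neighborhood into more than
#'   one connected component; keeps cells cohesive (no pinch-off) at the
#'   working temperature.
#' @param lamellipodia_blocked when `TRUE`, lamellipodium links that cycle
#'   are removed but never re-formed (the in-silico analogue of blocking
#'   lamellipodia with a function-blocking antibody).
#' @param reach_tolerance in-plane centroid-anchor distance (voxels) at which
#'   a lamellipodium link counts as satisfied and stops exerting tension.
#' @param seed default base seed for experiments.
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(contact_energy = contact_energy_table(),
                       lambda_volume = 2,
                       v_target = 125,
                       temperature = 16,
                       lambda_tissue = 150,
                       lambda_lamellipodia = 1200,
                       lambda_follower_substrate = 30,
                       zeta_lamellipodia = 0.08,
                       zeta_substrate = 0.2,
                       zeta_tissue = 0,
                       chi_lamellipodia = 12,
                       kappa = 6,
                       link_target_length = 5,
                       substrate_link_target_length = 3,
                       max_reformed_neighbors = 4,
                       mcs_per_sample = 200,
                       seconds_per_mcs = 5,
                       microns_per_voxel = 6,
                       bias_toward = c("far", "near"),
                       leader_rows = c("bottom", "full_face"),
                       connectivity_constraint = TRUE,
                       lamellipodia_blocked = FALSE,
                       reach_tolerance = 1,
                       seed = 1L) {
  cfg <- list(
    contact_energy = contact_energy,
    lambda_volume = lambda_volume,
    v_target = v_target,
    temperature = temperature,
    lambda_tissue = lambda_tissue,
    lambda_lamellipodia = lambda_lamellipodia,
    lambda_follower_substrate = lambda_follower_substrate,
    zeta_lamellipodia = zeta_lamellipodia,
    zeta_substrate = zeta_substrate,
    zeta_tissue = zeta_tissue,
    chi_lamellipodia = chi_lamellipodia,
    kappa = kappa,
    link_target_length = link_target_length,
    substrate_link_target_length = substrate_link_target_length,
    max_reformed_neighbors = as.integer(max_reformed_neighbors),
    mcs_per_sample = as.integer(mcs_per_sample),
    seconds_per_mcs = seconds_per_mcs,
    microns_per_voxel = microns_per_voxel,
    bias_toward = match.arg(bias_toward),
    leader_rows = match.arg(leader_rows),
    connectivity_constraint = isTRUE(connectivity_constraint),
    lamellipodia_blocked = isTRUE(lamellipodia_blocked),
    reach_tolerance = reach_tolerance,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param config a `sim_config` object or plain named list with its fields.
#' @return the validated config, invisibly classed as `sim_config`.
#' @export
validate_sim_config <- function(config) {
  J <- config$contact_energy
  stopifnot(is.matrix(J), nrow(J) == 4, ncol(J) == 4)
  if (max(abs(J - t(J))) > 1e-12) stop("contact_energy must be symmetric")
  if (config$temperature <= 0) stop("temperature must be > 0")
  if (config$v_target <= 0) stop("v_target must be > 0")
  for (z in c("zeta_lamellipodia", "zeta_substrate", "zeta_tissue"))
    if (config[[z]] < 0) stop(z, " must be >= 0")
  if (config$kappa < -6 || config$kappa > 6) stop("kappa must be in [-6, 6]")
  if (config$chi_lamellipodia < 0) stop("chi_lamellipodia must be >= 0")
  if (config$max_reformed_neighbors < 1) stop("max_reformed_neighbors must be >= 1")
  if (!config$bias_toward %in% c("far", "near")) stop("bias_toward must be 'far' or 'near'")
  class(config) <- "sim_config"
  config
}

#' Modify a configuration
#'
#' Returns a copy of `config` with the named fields replaced and re-validated.
#'
#' @param config a `sim_config`.
#' @param ... named fields to replace.
#' @export
update_config <- function(config, ...) {
  repl <- list(...)
  for (nm in names(repl)) {
    if (!nm %in% names(config)) stop("unknown config field: ", nm)
    config[[nm]] <- repl[[nm]]
  }
  validate_sim_config(config)
}

#' Read / write a configuration as YAML
#'
#' The YAML file mirrors the `sim_config` field names exactly; the contact
#' matrix is stored row-wise with its type labels.
#'
#' @param path file path.
#' @rdname config_io
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  J <- do.call(rbind, raw$contact_energy)
  types <- c("medium", "substrate", "leader", "follower")
  dimnames(J) <- list(types, types)
  raw$contact_energy <- J
  base <- sim_config()
  for (nm in names(base)) if (is.null(raw[[nm]])) raw[[nm]] <- base[[nm]]
  raw <- raw[names(base)]
  validate_sim_config(raw)
}

#' @param config a `sim_config` to serialize.
#' @rdname config_io
#' @export
write_sim_config <- function(config, path) {
  out <- unclass(config)
  out$contact_energy <- lapply(seq_len(4), function(i) unname(config$contact_energy[i, ]))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  temperature:", x$temperature, " lambda_volume:", x$lambda_volume,
      " v_target:", x$v_target, "\n")
  cat("  lambda: tissue", x$lambda_tissue, "| lamellipodia", x$lambda_lamellipodia,
      "| follower-substrate", x$lambda_follower_substrate, "\n")
  cat("  zeta:   lamellipodia", x$zeta_lamellipodia, "| substrate", x$zeta_substrate,
      "| tissue", x$zeta_tissue, "\n")
  cat("  chi_lamellipodia:", x$chi_lamellipodia, " kappa:", x$kappa,
      " bias_toward:", x$bias_toward, "\n")
  invisible(x)
}
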
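#' Total effective energy of a state
#'
#' Evaluates the effective-energy functional: the contact term summed over
#' 26-neighborhood voxel pairs with unequal owners, the quadratic volume
#' constraint `lambda_volume * (V_cell - V_target)^2` per cell, and the
#' mechanical link energies (elastic `lambda * (l - L)^2` for cell-cell and
#' follower-substrate links, constant-tension `lambda * l` for unsatisfied
#' lamellipodium links).
#'
#' @param state a [cpm_state][new_cpm_state].
#' @param config a [sim_config()].
#' @return scalar energy.
#' @export
compute_total_energy <- function(state, config) {
  cpp_total_energy(as_engine_state(state), as_engine_config(config))
}

#' Energy change of a hypothetical voxel copy
#'
#' Computes `H(after) - H(before)` for the copy of `source`'s owner into the
#' `target` voxel, incrementally: the local contact change over the target's
#' 26-neighborhood, the volume terms of the two affected cells, and the link
#' energies moved by their centroid shifts. The state is not modified.
#'
#' @param state a `cpm_state`.
#' @param config a `sim_config`.
#' @param source,target 1-based voxel coordinates (length-3 integer vectors);
#'   must be lattice neighbors with different owners, neither on the
#'   substrate plane.
#' @return scalar energy difference.
#' @export
delta_energy <- function(state, config, source, target) {
  cpp_delta_energy(as_engine_state(state), as_engine_config(config),
                   as.integer(source), as.integer(target))
}

#' Boltzmann acceptance probability
#'
#' A voxel copy that decreases (or leaves unchanged) the effective energy is
#' always accepted; an increase is accepted with probability
#' `exp(-delta_h / temperature)`.
#'
#' @param delta_h energy change(s) of the attempted copy.
#' @param temperature Cellular-Potts fluctuation amplitude, > 0.
#' @return acceptance probability in `[0, 1]`, vectorized over `delta_h`.
#' @export
acceptance_probability <- function(delta_h, temperature) {
  if (temperature <= 0) stop("temperature must be > 0")
  ifelse(delta_h <= 0, 1, exp(-delta_h / temperature))
}

#' Run the Cellular-Potts engine
#'
#' Advances the state by `n_mcs` Monte-Carlo steps. One MCS performs N
#' voxel-copy attempts (N = number of non-substrate lattice sites), each
#' drawing a random site and a random 6-neighbor source, then executes the
#' per-timestep link dynamics: lamellipodium cycling with cohesotaxis-biased
#' placement, follower-substrate re-anchoring, and cell-cell link
#' break/reform turnover (intercalation). Centroid trajectories, substrate
#' occupancy and (optionally) the free area of a gap region are sampled every
#' `sample_every` steps.
#'
#' @param state a `cpm_state`.
#' @param config a `sim_config`.
#' @param n_mcs number of Monte-Carlo steps (1 MCS = 5 s).
#' @param seed integer seed for the engine's random stream.
#' @param sample_every sampling interval in MCS; defaults to
#'   `config$mcs_per_sample`. `0` records only the initial and final states.
#' @param gap optional 1-based gap bounds `c(x0, x1, y0, y1)` whose free
#'   (medium) area at the substrate-adjacent layer is recorded per sample.
#' @param stop_when_closed stop at the first sample where the gap area has
#'   fallen to `close_threshold` or below.
#' @param close_threshold free-area level (voxel columns) treated as closed;
#'   collided explant edges leave a thin seam of medium columns, so effective
#'   closure is reached before the measured area is exactly zero.
#' @return a list of class `cpm_run` with elements `state` (the advanced
#'   `cpm_state`), `trajectory` (data.frame: sample, mcs, cell, type, x, y, z),
#'   `series` (per-sample data.frame: mcs, substrate_cells, free_area,
#'   acceptance, n_lamellipodium, n_cell_cell), `volumes`, `alive`,
#'   `acceptance_overall`, `n_breaks`, `n_reforms`, `closed`.
#' @export
run_cpm <- function(state, config, n_mcs, seed,
                    sample_every = config$mcs_per_sample,
                    gap = NULL, stop_when_closed = FALSE, close_threshold = 0) {
  res <- cpp_run(as_engine_state(state), as_engine_config(config),
                 as.integer(n_mcs), as.integer(seed), as.integer(sample_every),
                 if (is.null(gap)) integer(0) else as.integer(gap),
                 isTRUE(stop_when_closed), as.integer(close_threshold))
  new_state <- new_cpm_state(res$owner, state$cell_type,
                             links_from_engine(res$links),
                             mcs = res$mcs, meta = state$meta)
  ncell <- length(state$cell_type)
  cent <- res$samples$centroid
  nsamp <- dim(cent)[1]
  traj <- data.frame(
    sample = rep(seq_len(nsamp), times = ncell),
    mcs = rep(res$samples$mcs, times = ncell),
    cell = rep(seq_len(ncell), each = nsamp),
    type = rep(state$cell_type, each = nsamp),
    x = as.vector(cent[, , 1]),
    y = as.vector(cent[, , 2]),
    z = as.vector(cent[, , 3]),
    stringsAsFactors = FALSE)
  series <- data.frame(
    sample = seq_len(nsamp),
    mcs = res$samples$mcs,
    substrate_cells = res$samples$substrate_cells,
    free_area = res$samples$free_area,
    acceptance = res$samples$acceptance,
    n_lamellipodium = res$samples$n_lamellipodium,
    n_cell_cell = res$samples$n_cell_cell)
  structure(list(state = new_state, trajectory = traj, series = series,
                 volumes = res$volumes, alive = res$alive,
                 acceptance_overall = res$acceptance_overall,
                 n_breaks = res$n_breaks, n_reforms = res$n_reforms,
                 closed = res$closed),
            class = "cpm_run")
}

#' Advance a state by one (or a few) Monte-Carlo steps
#'
#' Thin wrapper over [run_cpm()] without intermediate sampling; returns the
#' advanced state only.
#'
#' @inheritParams run_cpm
#' @export
monte_carlo_step <- function(state, config, seed, n_mcs = 1) {
  run_cpm(state, config, n_mcs = n_mcs, seed = seed, sample_every = 0)$state
}

#' @export
print.cpm_run <- function(x, ...) {
  cat("<cpm_run> mcs:", x$state$mcs,
      "| samples:", nrow(x$series),
      "| acceptance:", signif(x$acceptance_overall, 3),
      "| live cells:", sum(x$alive), "\n")
  invisible(x)
}
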
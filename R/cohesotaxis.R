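#' Free-edge voxels of a cell
#'
#' A cell's voxels in face contact with medium (not other cells or the
#' substrate) - the sites through which lamellipodia may protrude. Returned
#' in deterministic lexicographic (x, y, z) order.
#'
#' @param state a `cpm_state`.
#' @param cell_id a live cell ID.
#' @return integer matrix with columns x, y, z (1-based voxel coordinates).
#' @export
free_edge_voxels <- function(state, cell_id) {
  m <- cpp_free_edge_voxels(as_engine_state(state), as_engine_config(sim_config()),
                            as.integer(cell_id))
  colnames(m) <- c("x", "y", "z")
  m
}

#' Cell-cell border voxels of a cell
#'
#' The cell's voxels with at least one face neighbor owned by a *different
#' cell* (medium and substrate excluded): the sites of cell-cell adhesion
#' that the cohesotaxis rule steers protrusions away from.
#'
#' @inheritParams free_edge_voxels
#' @return integer matrix with columns x, y, z.
#' @export
cell_border_voxels <- function(state, cell_id) {
  m <- cpp_cell_border_voxels(as_engine_state(state), as_engine_config(sim_config()),
                              as.integer(cell_id))
  colnames(m) <- c("x", "y", "z")
  m
}

#' Cumulative distance from a voxel to a cell's border voxels
#'
#' Sum of Euclidean distances from `voxel` to every cell-cell border voxel.
#' Free-edge voxels are ranked by this quantity: under the default
#' `bias_toward = "far"` reading, protrusion mass concentrates on the voxels
#' farthest (in cumulative distance) from cell-cell contacts. An empty border
#' set yields 0 (uniform ranking; selection falls back to unbiased).
#'
#' @param voxel numeric length-3 coordinate.
#' @param border_voxels matrix with one border voxel per row (columns x, y, z).
#' @return scalar cumulative distance.
#' @export
cumulative_border_distance <- function(voxel, border_voxels) {
  if (is.null(border_voxels) || nrow(border_voxels) == 0) return(0)
  d <- sweep(border_voxels[, 1:3, drop = FALSE], 2, as.numeric(voxel[1:3]))
  sum(sqrt(rowSums(d^2)))
}

#' Cohesotaxis bias weights
#'
#' The normalized sigmoid weight vector used to sample from a sorted list of
#' free-edge voxels. A logistic `f(x) = 1 / (1 + exp(-s x))` with steepness
#' `s = 2^kappa` is evaluated at `n` evenly spaced points over the fixed
#' window `[-5, 5]` (the single point `x = 0` when `n = 1`) and normalized to
#' sum 1. `kappa = -6` is nearly flat (no migratory bias); `kappa = 6`
#' approaches a step that places all mass at the high-index end.
#'
#' @param n list length (>= 1).
#' @param kappa bias parameter in `[-6, 6]`.
#' @return numeric weight vector of length `n`, summing to 1, monotone
#'   non-decreasing along the list.
#' @export
bias_weights <- function(n, kappa) {
  if (n < 1) stop("n must be >= 1")
  if (kappa < -6 || kappa > 6) stop("kappa must be in [-6, 6]")
  cpp_bias_weights(as.integer(n), kappa)
}

#' Select a direction voxel for a new lamellipodium
#'
#' Sorts the cell's free-edge voxels by cumulative distance to its cell-cell
#' border voxels (ascending, ties broken lexicographically) and samples one
#' index from [bias_weights()]. Because the weights increase along the sorted
#' list, probability mass concentrates on the voxels most opposite the
#' cell-cell contacts - i.e. in the direction of migration - with strength
#' controlled by `kappa`. With an empty border set the selection is uniform.
#'
#' @param state a `cpm_state`.
#' @param config a `sim_config` (supplies `kappa` and `bias_toward` defaults).
#' @param cell_id a live cell with at least one free-edge voxel.
#' @param kappa bias parameter; defaults to `config$kappa`.
#' @param u optional uniform variate in `[0, 1)` driving the draw (defaults
#'   to R's RNG); exposing it keeps the selection testable in isolation.
#' @return integer length-3 voxel coordinate.
#' @export
select_direction_voxel <- function(state, config, cell_id,
                                   kappa = config$kappa, u = runif(1)) {
  v <- cpp_select_direction_voxel(as_engine_state(state), as_engine_config(config),
                                  as.integer(cell_id), kappa,
                                  config$bias_toward == "far", u)
  setNames(v, c("x", "y", "z"))
}
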
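#' Elastic link energy
#'
#' Hookean energy `lambda * (l - L)^2` of a cell-cell or follower-substrate
#' link, with `l` the Euclidean distance between the two endpoints.
#'
#' @param link a one-row link table (or list) with `lambda` and
#'   `target_length`.
#' @param a,b numeric length-3 endpoint positions (centroid, or anchor for
#'   substrate links), voxel units.
#' @return scalar energy.
#' @export
elastic_energy <- function(link, a, b) {
  l <- sqrt(sum((as.numeric(a) - as.numeric(b))^2))
  link$lambda * (l - link$target_length)^2
}

#' Constant-tension lamellipodium energy
#'
#' Energy `lambda * l`, linear in the centroid-anchor distance, so the
#' traction force magnitude is length-independent. A satisfied link (the
#' leader has reached its anchor) exerts no energy until turnover replaces it.
#'
#' @param link a one-row link table (or list) with `lambda` and `satisfied`.
#' @param centroid,anchor numeric length-3 positions.
#' @return scalar energy.
#' @export
tension_energy <- function(link, centroid, anchor) {
  if (isTRUE(link$satisfied)) return(0)
  l <- sqrt(sum((as.numeric(centroid) - as.numeric(anchor))^2))
  link$lambda * l
}

#' Poisson turnover draw
#'
#' A link extension-retraction (or break) event fires this timestep with
#' probability `P = 1 - exp(-zeta)` (unit timestep). Uses R's RNG.
#'
#' @param zeta Poisson rate per timestep, >= 0.
#' @param n number of independent draws.
#' @return logical vector of length `n`.
#' @export
turnover_fires <- function(zeta, n = 1) {
  if (zeta < 0) stop("zeta must be >= 0")
  if (zeta == 0) return(rep(FALSE, n))
  runif(n) < (1 - exp(-zeta))
}

#' Mark a lamellipodium link satisfied
#'
#' A leader migrates toward its lamellipodium anchor and stops once it
#' arrives: when the in-plane (x, y) distance between the cell centroid and
#' the anchor falls within `tol`, the link is flagged satisfied and exerts
#' zero energy until the next turnover event replaces it.
#'
#' @param link one-row link table with anchor columns and `satisfied`.
#' @param centroid numeric length-3 cell centroid.
#' @param tol reach tolerance in voxels.
#' @return the link with `satisfied` updated.
#' @export
mark_satisfied <- function(link, centroid, tol = 1) {
  d <- sqrt((centroid[1] - link$anchor_x)^2 + (centroid[2] - link$anchor_y)^2)
  if (d <= tol) link$satisfied <- TRUE
  link
}

# anchor position for a new lamellipodium: chi voxels beyond the selected
# free-edge voxel along the centroid -> voxel direction, projected onto the
# substrate plane and clamped to the lattice.
lamellipodium_anchor <- function(state, config, centroid, voxel) {
  d <- as.numeric(voxel)[1:2] - as.numeric(centroid)[1:2]
  nrm <- sqrt(sum(d^2))
  if (nrm < 1e-9) {
    th <- runif(1) * 2 * pi
    d <- c(cos(th), sin(th))
    nrm <- 1
  }
  a <- as.numeric(voxel)[1:2] + config$chi_lamellipodia * d / nrm
  dm <- dim(state$owner)
  c(x = min(max(a[1], 1), dm[1]), y = min(max(a[2], 1), dm[2]), z = 1)
}

add_link_row <- function(state, kind, a, b = NA_integer_, anchor = c(NA, NA, NA),
                         lambda, target_length = 0) {
  row <- data.frame(kind = kind, a = as.integer(a), b = as.integer(b),
                    anchor_x = anchor[1], anchor_y = anchor[2], anchor_z = anchor[3],
                    lambda = lambda, target_length = target_length,
                    age = 0L, satisfied = FALSE, stringsAsFactors = FALSE)
  state$links <- rbind(state$links, row)
  rownames(state$links) <- NULL
  state
}

#' Cycle a leader's lamellipodium link
#'
#' Single-cell form of the per-timestep lamellipodium dynamics: with
#' probability `1 - exp(-zeta_lamellipodia)` the existing lamellipodium link
#' (if any) is deleted and, unless lamellipodia are blocked, a new one is
#' created through a cohesotaxis-selected free-edge voxel, anchored on the
#' substrate plane `chi_lamellipodia` voxels beyond it. A leader with no
#' free edge (fully surrounded by other cells) creates nothing and behaves
#' effectively as a follower. Uses R's RNG.
#'
#' @param state a `cpm_state`.
#' @param config a `sim_config`.
#' @param cell_id a leader cell ID.
#' @return the updated `cpm_state`.
#' @export
cycle_lamellipodium <- function(state, config, cell_id) {
  if (state$cell_type[cell_id] != "leader") stop("cell is not a leader")
  if (!turnover_fires(config$zeta_lamellipodia)) return(state)
  idx <- which(state$links$kind == "lamellipodium" & state$links$a == cell_id)
  if (length(idx)) state$links <- state$links[-idx, , drop = FALSE]
  if (config$lamellipodia_blocked) return(state)
  fe <- free_edge_voxels(state, cell_id)
  if (nrow(fe) == 0) return(state)
  v <- select_direction_voxel(state, config, cell_id)
  cen <- unlist(cell_table(state)[cell_id, c("x", "y", "z")])
  anchor <- lamellipodium_anchor(state, config, cen, v)
  add_link_row(state, "lamellipodium", cell_id, anchor = anchor,
               lambda = config$lambda_lamellipodia)
}

#' Cycle a follower's substrate link
#'
#' Only followers holding at least one voxel adjacent to the substrate plane
#' carry a follower-substrate link. If the follower has substrate contact and
#' no link, one is created anchored directly beneath its centroid; with
#' probability `1 - exp(-zeta_substrate)` an existing link re-anchors beneath
#' the current centroid. A follower that has lost substrate contact loses its
#' link. Uses R's RNG.
#'
#' @inheritParams cycle_lamellipodium
#' @param cell_id a follower cell ID.
#' @return the updated `cpm_state`.
#' @export
cycle_follower_substrate <- function(state, config, cell_id) {
  if (state$cell_type[cell_id] != "follower") stop("cell is not a follower")
  ct <- cell_table(state)
  idx <- which(state$links$kind == "follower_substrate" & state$links$a == cell_id)
  if (!ct$substrate_contact[cell_id]) {
    if (length(idx)) state$links <- state$links[-idx, , drop = FALSE]
    return(state)
  }
  cen <- unlist(ct[cell_id, c("x", "y")])
  if (length(idx) == 0) {
    return(add_link_row(state, "follower_substrate", cell_id,
                        anchor = c(cen[1], cen[2], 1),
                        lambda = config$lambda_follower_substrate,
                        target_length = config$substrate_link_target_length))
  }
  if (turnover_fires(config$zeta_substrate)) {
    state$links$anchor_x[idx] <- cen[1]
    state$links$anchor_y[idx] <- cen[2]
    state$links$age[idx] <- 0L
  }
  state
}
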
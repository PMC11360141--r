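#' Explant geometry specification
#'
#' A DMZ explant is a rectangular slab of cubic cells: 8 cells wide, 4 long
#' (along the migration axis) and 2 high, each cell a 5x5x5-voxel cube
#' (about 30x30x30 um), resting on the substrate.
#'
#' @param width_cells,length_cells,height_cells slab dimensions in cells.
#' @param voxels_per_cell_edge edge of the initial cubic cell, voxels.
#' @return an `explant_spec` list.
#' @export
explant_spec <- function(width_cells = 8, length_cells = 4, height_cells = 2,
                         voxels_per_cell_edge = 5) {
  structure(list(width_cells = width_cells, length_cells = length_cells,
                 height_cells = height_cells,
                 voxels_per_cell_edge = voxels_per_cell_edge),
            class = "explant_spec")
}

#' Build an empty lattice with its substrate plane
#'
#' The lowest z-layer is the immutable substrate; everything else is medium.
#' Lattice boundaries are fixed walls (no periodic wrap).
#'
#' @param dims integer length-3 lattice dimensions (voxels).
#' @return a `cpm_state` with no cells.
#' @export
build_substrate <- function(dims) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 2))
  owner <- array(0L, dim = dims)
  owner[, , 1] <- -1L
  new_cpm_state(owner, character(0))
}

facing_axis <- function(facing) {
  switch(facing,
         "+x" = c(1, 0, 0), "-x" = c(-1, 0, 0),
         "+y" = c(0, 1, 0), "-y" = c(0, -1, 0),
         stop("facing must be one of '+x', '-x', '+y', '-y'"))
}

#' Place a DMZ explant on the lattice
#'
#' Carves `width x length x height` cubic cells into the medium with their
#' bottom layer on the substrate. The leading-edge cells (the row facing the
#' migration direction) of the bottom layer - eight cells under the default
#' spec - are leaders; all others are followers (`leader_rows = "full_face"`
#' in the config promotes the whole leading face). Cell-cell links join every
#' face-adjacent cell pair; bottom-layer followers get substrate links
#' anchored beneath their centroids. Initial lamellipodium links are *not*
#' created here - call [init_lamellipodia()] once all explants are placed.
#'
#' @param state a `cpm_state` (typically from [build_substrate()]).
#' @param config a `sim_config`.
#' @param origin 1-based (x, y) voxel coordinates of the explant footprint's
#'   lower corner; cells occupy z-layers 2 onward.
#' @param facing migration direction, one of `"+x"`, `"-x"`, `"+y"`, `"-y"`.
#' @param spec an [explant_spec()].
#' @return the updated `cpm_state`; `meta$explants` gains an entry recording
#'   cell IDs, leader IDs, the leading bottom row in width order, the center
#'   four leading cells, and the facing axis.
#' @export
build_dmz <- function(state, config, origin, facing = "+y",
                      spec = explant_spec()) {
  axis <- facing_axis(facing)
  k <- spec$voxels_per_cell_edge
  along_x <- abs(axis[1]) == 1
  nxc <- if (along_x) spec$length_cells else spec$width_cells
  nyc <- if (along_x) spec$width_cells else spec$length_cells
  nzc <- spec$height_cells
  dm <- dim(state$owner)
  x1 <- origin[1] + nxc * k - 1
  y1 <- origin[2] + nyc * k - 1
  z1 <- 1 + nzc * k
  if (origin[1] < 1 || origin[2] < 1 || x1 > dm[1] || y1 > dm[2] || z1 > dm[3])
    stop("explant does not fit inside the lattice")

  id0 <- length(state$cell_type)
  grid <- array(0L, dim = c(nxc, nyc, nzc))
  n_new <- nxc * nyc * nzc
  ids <- id0 + seq_len(n_new)
  ctype <- rep("follower", n_new)
  owner <- state$owner
  i <- 0
  cen <- matrix(0, n_new, 3)
  for (iz in seq_len(nzc)) for (iy in seq_len(nyc)) for (ix in seq_len(nxc)) {
    i <- i + 1
    xs <- origin[1] + (ix - 1) * k + 0:(k - 1)
    ys <- origin[2] + (iy - 1) * k + 0:(k - 1)
    zs <- 1 + (iz - 1) * k + 1:k
    if (any(owner[xs, ys, zs] != 0)) stop("explant overlaps existing cells")
    owner[xs, ys, zs] <- ids[i]
    grid[ix, iy, iz] <- ids[i]
    cen[i, ] <- c(mean(xs), mean(ys), mean(zs))
  }

  lead_ix <- switch(facing, "+x" = nxc, "-x" = 1L, NA_integer_)
  lead_iy <- switch(facing, "+y" = nyc, "-y" = 1L, NA_integer_)
  lead_layers <- if (config$leader_rows == "full_face") seq_len(nzc) else 1L
  is_lead <- function(ix, iy, iz) {
    iz %in% lead_layers &&
      ((along_x && ix == lead_ix) || (!along_x && iy == lead_iy))
  }
  i <- 0
  for (iz in seq_len(nzc)) for (iy in seq_len(nyc)) for (ix in seq_len(nxc)) {
    i <- i + 1
    if (is_lead(ix, iy, iz)) ctype[i] <- "leader"
  }
  state$owner <- owner
  state$cell_type <- c(state$cell_type, ctype)

  # cell-cell links between all face-adjacent cell pairs of the slab
  for (iz in seq_len(nzc)) for (iy in seq_len(nyc)) for (ix in seq_len(nxc)) {
    a <- grid[ix, iy, iz]
    if (ix < nxc) state <- add_link_row(state, "cell_cell", a, grid[ix + 1, iy, iz],
                                        lambda = config$lambda_tissue,
                                        target_length = config$link_target_length)
    if (iy < nyc) state <- add_link_row(state, "cell_cell", a, grid[ix, iy + 1, iz],
                                        lambda = config$lambda_tissue,
                                        target_length = config$link_target_length)
    if (iz < nzc) state <- add_link_row(state, "cell_cell", a, grid[ix, iy, iz + 1],
                                        lambda = config$lambda_tissue,
                                        target_length = config$link_target_length)
  }

  # substrate links for bottom-layer followers, anchored beneath centroids
  i <- 0
  for (iz in seq_len(nzc)) for (iy in seq_len(nyc)) for (ix in seq_len(nxc)) {
    i <- i + 1
    if (iz == 1 && ctype[i] == "follower")
      state <- add_link_row(state, "follower_substrate", ids[i],
                            anchor = c(cen[i, 1], cen[i, 2], 1),
                            lambda = config$lambda_follower_substrate,
                            target_length = config$substrate_link_target_length)
  }

  bottom_lead <- if (along_x) grid[lead_ix, , 1] else grid[, lead_iy, 1]
  wpos <- seq_along(bottom_lead) # already ordered along the width axis
  nmid <- length(bottom_lead)
  center4 <- bottom_lead[wpos > (nmid / 2 - 2) & wpos <= (nmid / 2 + 2)]
  leaders <- ids[ctype == "leader"]
  state$meta$explants <- c(state$meta$explants, list(list(
    facing = facing, axis = axis, origin = origin, spec = spec,
    cell_ids = ids, grid = grid, leader_ids = leaders,
    leading_row_bottom = bottom_lead, center4 = center4)))
  state
}

#' Create initial lamellipodium links
#'
#' At initialization every leader extends one constant-tension link through a
#' *uniformly* chosen free-edge voxel (no cohesotaxis bias at time zero) to
#' establish an initial forward direction. Leaders without a free edge are
#' skipped. Uses R's RNG.
#'
#' @param state a `cpm_state` with all explants placed.
#' @param config a `sim_config`.
#' @return the updated `cpm_state`.
#' @export
init_lamellipodia <- function(state, config) {
  ct <- cell_table(state)
  for (id in which(state$cell_type == "leader")) {
    fe <- free_edge_voxels(state, id)
    if (nrow(fe) == 0) next
    v <- fe[sample.int(nrow(fe), 1), ]
    anchor <- lamellipodium_anchor(state, config,
                                   unlist(ct[id, c("x", "y", "z")]), v)
    state <- add_link_row(state, "lamellipodium", id, anchor = anchor,
                          lambda = config$lambda_lamellipodia)
  }
  state
}

preset_margins <- function(preset) {
  switch(preset,
         standard = list(side = 14L, back = 6L, front = 52L, top = 5L, itr_margin = 6L),
         reduced = list(side = 12L, back = 4L, front = 52L, top = 2L, itr_margin = 3L),
         stop("preset must be 'standard' or 'reduced'"))
}

#' Ready-to-run single-DMZ state
#'
#' Builds a lattice sized for the 2-h migration protocol (free space ahead of
#' the leading edge exceeding twice the explant length), places one DMZ
#' explant facing `+y`, and creates the initial links. The `"reduced"` preset
#' trims the lateral margins and head-room to cut simulation cost without
#' touching the explant itself or the migration room.
#'
#' @param config a `sim_config`.
#' @param seed integer seed for the initial lamellipodium directions.
#' @param spec an [explant_spec()].
#' @param preset `"standard"` or `"reduced"` lattice sizing.
#' @return a `cpm_state`; `meta$explants[[1]]` describes the explant.
#' @export
dmz_state <- function(config, seed = config$seed, spec = explant_spec(),
                      preset = "standard") {
  m <- preset_margins(preset)
  k <- spec$voxels_per_cell_edge
  wv <- spec$width_cells * k
  lv <- spec$length_cells * k
  hv <- spec$height_cells * k
  dims <- c(wv + 2 * m$side, m$back + lv + m$front, 1 + hv + m$top)
  state <- build_substrate(dims)
  state <- build_dmz(state, config, origin = c(m$side + 1, m$back + 1),
                     facing = "+y", spec = spec)
  set.seed(seed)
  init_lamellipodia(state, config)
}

#' Ready-to-run in-the-round (ITR) state
#'
#' Places four DMZ explants orthogonal to one another, facing `+x`, `-x`,
#' `+y` and `-y` toward a central cell-free square of side `gap_size`
#' (default: one explant width). No other parameters change relative to the
#' single-explant model. The initial owner map has 4-fold rotational symmetry
#' about the gap center when `gap_size` equals the explant width.
#'
#' @inheritParams dmz_state
#' @param gap_size side of the central free square, voxels.
#' @return a `cpm_state`; `meta$gap` holds the 1-based gap bounds
#'   `c(x0, x1, y0, y1)` used for free-area measurement.
#' @export
itr_state <- function(config, seed = config$seed, spec = explant_spec(),
                      gap_size = spec$width_cells * spec$voxels_per_cell_edge,
                      preset = "standard") {
  m <- preset_margins(preset)
  k <- spec$voxels_per_cell_edge
  wv <- spec$width_cells * k
  lv <- spec$length_cells * k
  hv <- spec$height_cells * k
  side <- gap_size + 2 * lv + 2 * m$itr_margin
  dims <- c(side, side, 1 + hv + m$top)
  state <- build_substrate(dims)
  g0 <- m$itr_margin + lv + 1
  g1 <- g0 + gap_size - 1
  off <- floor((gap_size - wv) / 2)
  ow <- g0 + off # width-axis origin so explants are centered on the gap
  state <- build_dmz(state, config, origin = c(ow, m$itr_margin + 1), facing = "+y", spec = spec)
  state <- build_dmz(state, config, origin = c(ow, g1 + 1), facing = "-y", spec = spec)
  state <- build_dmz(state, config, origin = c(m$itr_margin + 1, ow), facing = "+x", spec = spec)
  state <- build_dmz(state, config, origin = c(g1 + 1, ow), facing = "-x", spec = spec)
  state$meta$gap <- c(g0, g1, g0, g1)
  set.seed(seed)
  init_lamellipodia(state, config)
}
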
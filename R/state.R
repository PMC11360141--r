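#' Simulation state container
#'
#' A `cpm_state` bundles the voxel lattice with the cell registry and the
#' mechanical link table. The lattice is a 3D integer array mapping each voxel
#' to its owner: `-1` for the immutable substrate plane (the lowest z-layer),
#' `0` for medium, and positive integers for cell IDs. Cell types never change
#' after initialization.
#'
#' @param owner integer 3D array of voxel owners.
#' @param cell_type character vector (`"leader"` / `"follower"`), one entry
#'   per cell ID.
#' @param links a link table as produced by [empty_links()].
#' @param mcs Monte-Carlo step counter.
#' @param meta free-form metadata list (explant layout, gap bounds, ...).
#' @return an object of class `cpm_state`.
#' @export
new_cpm_state <- function(owner, cell_type, links = empty_links(),
                          mcs = 0, meta = list()) {
  stopifnot(is.array(owner), length(dim(owner)) == 3)
  structure(list(owner = owner, cell_type = cell_type, links = links,
                 mcs = mcs, meta = meta),
            class = "cpm_state")
}

#' Empty mechanical link table
#'
#' One row per link. `kind` is one of `"cell_cell"` (elastic, between two
#' cell centroids), `"follower_substrate"` (elastic, centroid to a fixed
#' substrate anchor), or `"lamellipodium"` (constant tension, leader centroid
#' to a substrate anchor). Anchors are voxel-unit coordinates on the
#' substrate plane and never move once placed.
#'
#' @return a zero-row data.frame with the link-table columns.
#' @export
empty_links <- function() {
  data.frame(kind = character(0), a = integer(0), b = integer(0),
             anchor_x = numeric(0), anchor_y = numeric(0), anchor_z = numeric(0),
             lambda = numeric(0), target_length = numeric(0),
             age = integer(0), satisfied = logical(0),
             stringsAsFactors = FALSE)
}

link_kind_codes <- c(cell_cell = 0L, follower_substrate = 1L, lamellipodium = 2L)

# state/config marshalling for the C++ engine
as_engine_state <- function(state) {
  lk <- state$links
  list(owner = state$owner,
       cell_type = match(state$cell_type, c("leader", "follower")),
       links = list(kind = unname(link_kind_codes[lk$kind]),
                    a = as.integer(lk$a),
                    b = as.integer(lk$b),
                    anchor_x = as.numeric(lk$anchor_x),
                    anchor_y = as.numeric(lk$anchor_y),
                    anchor_z = as.numeric(lk$anchor_z),
                    lambda = as.numeric(lk$lambda),
                    target_length = as.numeric(lk$target_length),
                    age = as.integer(lk$age),
                    satisfied = as.logical(lk$satisfied)),
       mcs = state$mcs)
}

as_engine_config <- function(config) {
  cfg <- unclass(config)
  cfg$contact_energy <- unname(config$contact_energy)
  cfg
}

links_from_engine <- function(lk) {
  kinds <- names(link_kind_codes)[lk$kind + 1L]
  data.frame(kind = kinds, a = lk$a, b = lk$b,
             anchor_x = lk$anchor_x, anchor_y = lk$anchor_y, anchor_z = lk$anchor_z,
             lambda = lk$lambda, target_length = lk$target_length,
             age = lk$age, satisfied = lk$satisfied,
             stringsAsFactors = FALSE)
}

#' Per-cell summary table
#'
#' @param state a `cpm_state`.
#' @return data.frame with id, type, volume, centroid coordinates (voxel
#'   units), alive flag and substrate-contact flag. A removed cell (volume 0)
#'   keeps its row with `alive = FALSE`.
#' @export
cell_table <- function(state) {
  res <- cpp_cell_table(as_engine_state(state), as_engine_config(sim_config()))
  data.frame(id = res$id,
             type = c("leader", "follower")[res$type],
             volume = res$volume,
             x = res$x, y = res$y, z = res$z,
             alive = res$alive, substrate_contact = res$substrate_contact,
             stringsAsFactors = FALSE)
}

#' Number of cells in contact with the substrate
#'
#' Counts live cells holding at least one voxel face-adjacent to the
#' substrate plane. Used to quantify radial (top-down) intercalation.
#'
#' @param state a `cpm_state`.
#' @return integer count.
#' @export
substrate_cell_count <- function(state) {
  sum(cell_table(state)$substrate_contact)
}

#' Connected-component count per cell
#'
#' Face-connected components of each cell's voxel set; a cohesive cell has
#' exactly one. Used as the fragmentation gate during calibration.
#'
#' @param state a `cpm_state`.
#' @return integer vector indexed by cell ID (0 for removed cells).
#' @export
cell_component_counts <- function(state) {
  cpp_component_counts(as_engine_state(state), as_engine_config(sim_config()))
}

#' @export
print.cpm_state <- function(x, ...) {
  d <- dim(x$owner)
  ct <- table(factor(x$cell_type, levels = c("leader", "follower")))
  cat("<cpm_state> lattice", paste(d, collapse = "x"),
      "| cells:", length(x$cell_type),
      sprintf("(%d leaders, %d followers)", ct[["leader"]], ct[["follower"]]),
      "| links:", nrow(x$links), "| mcs:", x$mcs, "\n")
  invisible(x)
}

#' Export the link table to CSV
#'
#' @param state a `cpm_state`.
#' @param path output file.
#' @export
write_link_table <- function(state, path) {
  write.csv(state$links, path, row.names = FALSE)
  invisible(path)
}
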
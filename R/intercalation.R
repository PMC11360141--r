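#' Cells in lattice face-contact with a cell
#'
#' @param state a `cpm_state`.
#' @param cell_id a live cell ID.
#' @return sorted integer vector of adjacent cell IDs.
#' @export
adjacent_cells <- function(state, cell_id) {
  own <- state$owner
  dm <- dim(own)
  idx <- which(own == cell_id, arr.ind = TRUE)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  nb <- integer(0)
  for (k in seq_len(6)) {
    sh <- sweep(idx, 2, offs[k, ], "+")
    ok <- sh[, 1] >= 1 & sh[, 1] <= dm[1] & sh[, 2] >= 1 & sh[, 2] <= dm[2] &
      sh[, 3] >= 1 & sh[, 3] <= dm[3]
    o <- own[sh[ok, , drop = FALSE]]
    nb <- c(nb, o[o > 0 & o != cell_id])
  }
  sort(unique(nb))
}

#' Stochastic breakage of cell-cell links
#'
#' Each cell-cell link independently breaks this timestep with probability
#' `1 - exp(-zeta_tissue)` (its lifetime is a Poisson process). Uses R's RNG.
#'
#' @param links a link table.
#' @param zeta_tissue Poisson break rate per timestep, >= 0.
#' @return integer row indices (into `links`) of the links that break.
#' @export
maybe_break_cell_links <- function(links, zeta_tissue) {
  if (zeta_tissue < 0) stop("zeta_tissue must be >= 0")
  cc <- which(links$kind == "cell_cell")
  if (length(cc) == 0 || zeta_tissue == 0) return(integer(0))
  cc[turnover_fires(zeta_tissue, length(cc))]
}

#' Reform a cell-cell link after breakage
#'
#' Invoked once per broken link for the breaking cell: if the cell currently
#' holds fewer than `max_neighbors` cell-cell links, a new link (stiffness
#' `lambda`, target length `target_length`) is created to a uniformly random
#' lattice-adjacent cell that has no link to it yet and is itself below the
#' cap; otherwise nothing is created. Uses R's RNG.
#'
#' @param links a link table.
#' @param cell_id the cell attempting reformation.
#' @param candidate_neighbors integer IDs of lattice-adjacent cells
#'   (see [adjacent_cells()]).
#' @param max_neighbors cell-cell link cap (default 4).
#' @param lambda,target_length parameters of the new link.
#' @return the updated link table (unchanged when no link is formed).
#' @export
reform_link <- function(links, cell_id, candidate_neighbors,
                        max_neighbors = 4, lambda, target_length) {
  n_cc <- function(id) sum(links$kind == "cell_cell" & (links$a == id | links$b == id))
  if (n_cc(cell_id) >= max_neighbors) return(links)
  linked <- function(id) any(links$kind == "cell_cell" &
                               ((links$a == cell_id & links$b == id) |
                                  (links$b == cell_id & links$a == id)))
  elig <- candidate_neighbors[!vapply(candidate_neighbors, linked, logical(1))]
  elig <- elig[vapply(elig, n_cc, numeric(1)) < max_neighbors]
  if (length(elig) == 0) return(links)
  partner <- if (length(elig) == 1) elig else elig[sample.int(length(elig), 1)]
  row <- data.frame(kind = "cell_cell", a = as.integer(cell_id),
                    b = as.integer(partner),
                    anchor_x = NA_real_, anchor_y = NA_real_, anchor_z = NA_real_,
                    lambda = lambda, target_length = target_length,
                    age = 0L, satisfied = FALSE, stringsAsFactors = FALSE)
  out <- rbind(links, row)
  rownames(out) <- NULL
  out
}

#' One intercalation timestep
#'
#' Applies [maybe_break_cell_links()] then, per broken link, a single
#' [reform_link()] attempt by one endpoint of the broken link (chosen
#' uniformly). Cell-cell link turnover fluidizes the tissue and lets passive
#' rearrangement - including radial intercalation toward the substrate -
#' emerge from the voxel dynamics. Uses R's RNG.
#'
#' @param state a `cpm_state`.
#' @param config a `sim_config` (supplies `zeta_tissue`,
#'   `max_reformed_neighbors`, `lambda_tissue`, `link_target_length`).
#' @return the updated `cpm_state`.
#' @export
intercalation_step <- function(state, config) {
  broken <- maybe_break_cell_links(state$links, config$zeta_tissue)
  if (length(broken) == 0) return(state)
  ends <- state$links[broken, c("a", "b")]
  state$links <- state$links[-broken, , drop = FALSE]
  rownames(state$links) <- NULL
  for (i in seq_len(nrow(ends))) {
    chooser <- if (runif(1) < 0.5) ends$a[i] else ends$b[i]
    state$links <- reform_link(state$links, chooser,
                               adjacent_cells(state, chooser),
                               config$max_reformed_neighbors,
                               config$lambda_tissue, config$link_target_length)
  }
  state
}
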
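# Independent brute-force re-implementations used as oracles. These loop over
# the whole lattice / link table in plain R and share no code with the engine.

half_offsets_26 <- local({
  o <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  o <- o[!(o$dx == 0 & o$dy == 0 & o$dz == 0), ]
  o[o$dz > 0 | (o$dz == 0 & (o$dy > 0 | (o$dy == 0 & o$dx > 0))), ]
})

bf_tau <- function(state, o) {
  if (o == 0) return("medium")
  if (o == -1) return("substrate")
  state$cell_type[o]
}

bf_centroid <- function(state, id) {
  colMeans(which(state$owner == id, arr.ind = TRUE))
}

# term-by-term re-summation of the effective energy
bf_total_energy <- function(state, config) {
  own <- state$owner
  dm <- dim(own)
  H <- 0
  for (z in seq_len(dm[3])) for (y in seq_len(dm[2])) for (x in seq_len(dm[1])) {
    o <- own[x, y, z]
    for (k in seq_len(nrow(half_offsets_26))) {
      x2 <- x + half_offsets_26$dx[k]
      y2 <- y + half_offsets_26$dy[k]
      z2 <- z + half_offsets_26$dz[k]
      if (x2 < 1 || x2 > dm[1] || y2 < 1 || y2 > dm[2] || z2 < 1 || z2 > dm[3]) next
      o2 <- own[x2, y2, z2]
      if (o2 != o)
        H <- H + config$contact_energy[bf_tau(state, o), bf_tau(state, o2)]
    }
  }
  vols <- vapply(seq_along(state$cell_type), function(id) sum(own == id), numeric(1))
  H <- H + sum(config$lambda_volume * (vols[vols > 0] - config$v_target)^2)
  lk <- state$links
  for (i in seq_len(nrow(lk))) {
    row <- lk[i, ]
    if (vols[row$a] == 0) next
    ca <- bf_centroid(state, row$a)
    if (row$kind == "cell_cell") {
      if (vols[row$b] == 0) next
      H <- H + elastic_energy(row, ca, bf_centroid(state, row$b))
    } else if (row$kind == "follower_substrate") {
      H <- H + elastic_energy(row, ca, c(row$anchor_x, row$anchor_y, row$anchor_z))
    } else {
      H <- H + tension_energy(row, ca, c(row$anchor_x, row$anchor_y, row$anchor_z))
    }
  }
  H
}

# the state after owner(source) copies into target, with registry cleanup
bf_apply_copy <- function(state, source, target) {
  b <- state$owner[target[1], target[2], target[3]]
  state$owner[target[1], target[2], target[3]] <-
    state$owner[source[1], source[2], source[3]]
  if (b > 0 && sum(state$owner == b) == 0) {
    keep <- !(state$links$a == b | (state$links$kind == "cell_cell" & state$links$b == b))
    state$links <- state$links[keep, , drop = FALSE]
  }
  state
}

# random small lattice with blobby multi-voxel cells and a full link mix
random_test_state <- function(seed, dims = c(8, 8, 4), ncell = 3) {
  set.seed(seed)
  st <- build_substrate(dims)
  own <- st$owner
  repeat {
    free <- which(own != -1L)
    own[free] <- sample(0:ncell, length(free), replace = TRUE,
                        prob = c(0.5, rep(0.5 / ncell, ncell)))
    if (all(vapply(seq_len(ncell), function(id) sum(own == id), numeric(1)) >= 2)) break
  }
  st$owner <- own
  st$cell_type <- sample(c("leader", "follower"), ncell, replace = TRUE)
  st$cell_type[1] <- "leader"  # ensure both types occur
  st$cell_type[2] <- "follower"
  lam <- runif(1, 1, 5)
  for (pr in list(c(1, 2), c(2, 3)))
    st <- mesendosim:::add_link_row(st, "cell_cell", pr[1], pr[2],
                                    lambda = runif(1, 1, 10),
                                    target_length = runif(1, 1, 4))
  for (id in seq_len(ncell)) {
    anchor <- c(runif(1, 1, dims[1]), runif(1, 1, dims[2]), 1)
    if (st$cell_type[id] == "follower")
      st <- mesendosim:::add_link_row(st, "follower_substrate", id, anchor = anchor,
                                      lambda = runif(1, 1, 10),
                                      target_length = runif(1, 1, 3))
    else
      st <- mesendosim:::add_link_row(st, "lamellipodium", id, anchor = anchor,
                                      lambda = lam)
  }
  st
}

random_test_config <- function(seed) {
  set.seed(seed + 1000)
  J <- matrix(runif(16, 0, 8), 4, 4)
  J <- (J + t(J)) / 2
  types <- c("medium", "substrate", "leader", "follower")
  dimnames(J) <- list(types, types)
  sim_config(contact_energy = J,
             lambda_volume = runif(1, 0.5, 3),
             v_target = sample(5:20, 1),
             temperature = runif(1, 5, 30))
}

# a compact two-cell state used by behavioral engine tests
two_cell_state <- function(config, dims = c(16, 16, 8)) {
  st <- build_substrate(dims)
  own <- st$owner
  own[4:8, 6:10, 2:6] <- 1L
  own[9:13, 6:10, 2:6] <- 2L
  st$owner <- own
  st$cell_type <- c("follower", "follower")
  st
}
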
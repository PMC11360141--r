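make_leader_with_rear_contact <- function() {
  # leader cube with a follower directly behind it (-y side)
  st <- build_substrate(c(40, 40, 12))
  st$owner[18:22, 18:22, 2:6] <- 1L
  st$owner[18:22, 13:17, 2:6] <- 2L
  st$cell_type <- c("leader", "follower")
  st
}

test_that("free-edge voxels match a brute-force neighbor scan", {
  st <- build_substrate(c(20, 20, 12))
  st$owner[8:12, 8:12, 3:7] <- 1L  # isolated floating cube
  st$cell_type <- "follower"
  fe <- free_edge_voxels(st, 1)
  expect_equal(nrow(fe), 98)  # 5^3 - 3^3 surface voxels

  for (seed in 1:3) {
    rs <- random_test_state(seed)
    dm <- dim(rs$owner)
    for (id in 1:2) {
      vox <- which(rs$owner == id, arr.ind = TRUE)
      is_free <- apply(vox, 1, function(v) {
        for (k in 1:3) for (s in c(-1, 1)) {
          nb <- v; nb[k] <- nb[k] + s
          if (any(nb < 1) || any(nb > dm)) next
          if (rs$owner[nb[1], nb[2], nb[3]] == 0) return(TRUE)
        }
        FALSE
      })
      expected <- vox[is_free, , drop = FALSE]
      expected <- expected[order(expected[, 1], expected[, 2], expected[, 3]), ,
                           drop = FALSE]
      got <- free_edge_voxels(rs, id)
      expect_equal(unname(got), unname(expected))
    }
  }
})

test_that("enclosed cells have no free edge", {
  st <- build_substrate(c(9, 9, 6))
  st$owner[, , 2:5] <- 2L
  st$owner[4:6, 4:6, 2:3] <- 1L
  st$cell_type <- c("leader", "follower")
  expect_equal(nrow(free_edge_voxels(st, 1)), 0)
})

test_that("cumulative border distance sums Euclidean distances", {
  expect_equal(cumulative_border_distance(c(1, 1, 1), matrix(c(1, 1, 1), 1)), 0)
  b <- rbind(c(4, 1, 1), c(1, 5, 1))  # distances 3 and 4
  expect_equal(cumulative_border_distance(c(1, 1, 1), b), 7)
  expect_equal(cumulative_border_distance(c(1, 1, 1), NULL), 0)
  set.seed(4)
  v <- runif(3, 1, 10)
  b <- matrix(runif(30, 1, 10), ncol = 3)
  manual <- sum(apply(b, 1, function(r) sqrt(sum((r - v)^2))))
  expect_equal(cumulative_border_distance(v, b), manual)
})

test_that("bias weights are a normalized logistic over [-5, 5]", {
  expect_equal(bias_weights(1, 3), 1)
  w <- bias_weights(10, -6)
  expect_lt(max(w) - min(w), 0.02)  # kappa = -6 is nearly flat
  # frozen oracle values: logistic with s = 1 at x = -5, 0, 5, normalized
  f <- 1 / (1 + exp(-c(-5, 0, 5)))
  expect_equal(bias_weights(3, 0), f / sum(f), tolerance = 1e-9)
  expect_equal(bias_weights(3, 0), c(0.0044619, 0.3333333, 0.6622048),
               tolerance = 1e-6)
  expect_error(bias_weights(0, 0), "n")
  expect_error(bias_weights(5, 7), "kappa")
})

test_that("bias weights normalize and order correctly across the grid", {
  for (n in c(1:5, 10, 25, 50)) for (kappa in -6:6) {
    w <- bias_weights(n, kappa)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(diff(w) >= -1e-15))  # monotone non-decreasing
  }
})

test_that("probability mass in the top half is non-decreasing in kappa", {
  n <- 20
  top <- vapply(seq(-6, 6, 0.5), function(k) sum(bias_weights(n, k)[11:20]),
                numeric(1))
  expect_true(all(diff(top) >= -1e-12))
})

test_that("selection favors voxels opposite cell-cell contacts", {
  st <- make_leader_with_rear_contact()
  cfg <- sim_config()
  # with maximal bias (a saturated sigmoid), mass concentrates uniformly on
  # the far-from-contact half of the sorted list and vanishes on the near half
  fe <- free_edge_voxels(st, 1)
  border <- cell_border_voxels(st, 1)
  cum <- apply(fe, 1, cumulative_border_distance, border_voxels = border)
  thr <- stats::median(cum)
  set.seed(10)
  n_draw <- 2000
  us <- runif(n_draw)
  picks <- t(vapply(us, function(u) select_direction_voxel(st, cfg, 1, kappa = 6, u = u),
                    c(x = 0L, y = 0L, z = 0L)))
  pick_cum <- apply(picks, 1, cumulative_border_distance, border_voxels = border)
  expect_gte(mean(pick_cum >= thr), 0.95)
  # and the mean selected rank matches the weight vector's expectation
  n <- length(cum)
  w <- bias_weights(n, 6)
  # ties in the cumulative distances blur the rank estimate slightly
  ranks <- vapply(pick_cum, function(pc) mean(sort(cum) <= pc + 1e-9) , numeric(1))
  expect_equal(mean(ranks), sum(w * seq_len(n) / n), tolerance = 0.06)
})

test_that("kappa = -6 selection is uniform within multinomial tolerance", {
  st <- build_substrate(c(20, 20, 12))
  st$owner[8:12, 8:12, 3:7] <- 1L  # no cell-cell border: exactly uniform
  st$cell_type <- "leader"
  cfg <- sim_config()
  fe <- free_edge_voxels(st, 1)
  n <- nrow(fe)
  set.seed(11)
  n_draw <- 10000
  picks <- t(vapply(runif(n_draw),
                    function(u) select_direction_voxel(st, cfg, 1, kappa = -6, u = u),
                    c(x = 0L, y = 0L, z = 0L)))
  key <- picks[, 1] * 1e6 + picks[, 2] * 1e3 + picks[, 3]
  # count draws per third of the lexicographically sorted voxel list
  fe_key <- sort(fe[, 1] * 1e6 + fe[, 2] * 1e3 + fe[, 3])
  thirds <- cut(match(key, fe_key), breaks = c(0, n / 3, 2 * n / 3, n))
  counts <- table(thirds)
  exp_n <- n_draw / 3
  tol <- 3 * sqrt(n_draw * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - exp_n) < tol))
})

test_that("cohesotaxis ranking is equivariant under 90-degree rotation", {
  st <- make_leader_with_rear_contact()
  cfg <- sim_config()
  dmxy <- dim(st$owner)[1:2]
  rot <- st
  ownr <- array(0L, dim = dim(st$owner))
  for (z in seq_len(dim(st$owner)[3]))
    ownr[, , z] <- t(st$owner[, , z])[dmxy[2]:1, ]  # 90-degree rotation in xy
  rot$owner <- ownr
  border <- cell_border_voxels(st, 1)
  border_r <- cell_border_voxels(rot, 1)
  cum <- sort(apply(free_edge_voxels(st, 1), 1, cumulative_border_distance,
                    border_voxels = border))
  cum_r <- sort(apply(free_edge_voxels(rot, 1), 1, cumulative_border_distance,
                      border_voxels = border_r))
  expect_equal(cum, cum_r, tolerance = 1e-9)
  # the selected voxel occupies the same rank in the rotated configuration
  for (u in seq(0.1, 0.9, 0.2)) {
    v <- select_direction_voxel(st, cfg, 1, kappa = 4, u = u)
    vr <- select_direction_voxel(rot, cfg, 1, kappa = 4, u = u)
    expect_equal(cumulative_border_distance(v, border),
                 cumulative_border_distance(vr, border_r), tolerance = 1e-9)
  }
})

test_that("bias_toward = 'near' reverses the preference", {
  st <- make_leader_with_rear_contact()
  cfg <- update_config(sim_config(), bias_toward = "near")
  border <- cell_border_voxels(st, 1)
  fe <- free_edge_voxels(st, 1)
  cum <- apply(fe, 1, cumulative_border_distance, border_voxels = border)
  med <- stats::median(cum)
  set.seed(12)
  picks <- t(vapply(runif(500),
                    function(u) select_direction_voxel(st, cfg, 1, kappa = 6, u = u),
                    c(x = 0L, y = 0L, z = 0L)))
  pick_cum <- apply(picks, 1, cumulative_border_distance, border_voxels = border)
  expect_gt(mean(pick_cum <= med), 0.9)
})
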
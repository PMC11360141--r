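test_that("elastic link energy is the Hookean quadratic form", {
  lk <- list(lambda = 5, target_length = 3)
  expect_equal(elastic_energy(lk, c(0, 0, 0), c(3, 0, 0)), 0)    # at rest length
  lk0 <- list(lambda = 0, target_length = 3)
  expect_equal(elastic_energy(lk0, c(0, 0, 0), c(9, 9, 9)), 0)
  lk3 <- list(lambda = 3, target_length = 4)
  expect_equal(elastic_energy(lk3, c(0, 0, 0), c(6, 0, 0)), 12)  # 3 * 2^2
})

test_that("lamellipodium tension energy is linear with constant force", {
  lk <- list(lambda = 7, satisfied = FALSE)
  expect_equal(tension_energy(lk, c(1, 1, 1), c(1, 1, 1)), 0)
  e1 <- tension_energy(lk, c(0, 0, 0), c(4, 0, 0))
  e2 <- tension_energy(lk, c(0, 0, 0), c(8, 0, 0))
  expect_equal(e2, 2 * e1)
  # numeric derivative dE/dl equals lambda at several lengths
  h <- 1e-6
  for (l in c(2, 5, 9)) {
    dEdl <- (tension_energy(lk, c(0, 0, 0), c(l + h, 0, 0)) -
               tension_energy(lk, c(0, 0, 0), c(l - h, 0, 0))) / (2 * h)
    expect_equal(dEdl, 7, tolerance = 1e-6)
  }
  expect_equal(tension_energy(list(lambda = 7, satisfied = TRUE),
                              c(0, 0, 0), c(5, 0, 0)), 0)
})

test_that("Poisson turnover matches its closed-form probability", {
  expect_false(any(turnover_fires(0, 1000)))
  expect_error(turnover_fires(-1), ">= 0")
  set.seed(99)
  n <- 1e5
  zeta <- 0.1
  p <- 1 - exp(-zeta)
  hits <- sum(turnover_fires(zeta, n))
  expect_lt(abs(hits - n * p), 3 * sqrt(n * p * (1 - p)))
})

test_that("mark_satisfied uses the in-plane reach tolerance", {
  lk <- data.frame(anchor_x = 10, anchor_y = 10, satisfied = FALSE)
  expect_true(mark_satisfied(lk, c(10, 10, 4))$satisfied)   # exactly at anchor
  expect_true(mark_satisfied(lk, c(10.6, 10.6, 9))$satisfied) # z ignored
  expect_false(mark_satisfied(lk, c(13, 10, 4))$satisfied)
})

test_that("lamellipodium cycling deletes, re-forms and respects blocking", {
  cfg <- sim_config(zeta_lamellipodia = 50) # fires essentially always
  st <- build_substrate(c(45, 45, 10))
  st$owner[21:25, 21:25, 2:6] <- 1L
  st$cell_type <- "leader"
  set.seed(1)
  st2 <- cycle_lamellipodium(st, cfg, 1)
  expect_equal(sum(st2$links$kind == "lamellipodium"), 1)
  # anchor lies chi voxels beyond the selected free-edge voxel, in-plane
  cen <- unlist(cell_table(st)[1, c("x", "y", "z")])
  for (u in seq(0.005, 0.995, length.out = 100)) {
    v <- select_direction_voxel(st, cfg, 1, u = u)
    a <- mesendosim:::lamellipodium_anchor(st, cfg, cen, v)
    expect_equal(unname(sqrt((a[1] - v[1])^2 + (a[2] - v[2])^2)),
                 cfg$chi_lamellipodia, tolerance = 1e-9)
    expect_equal(unname(a[3]), 1)
  }

  cfg0 <- update_config(cfg, zeta_lamellipodia = 0)
  expect_identical(cycle_lamellipodium(st2, cfg0, 1)$links, st2$links)

  cfgb <- update_config(cfg, lamellipodia_blocked = TRUE)
  st3 <- cycle_lamellipodium(st2, cfgb, 1)
  expect_equal(sum(st3$links$kind == "lamellipodium"), 0)
})

test_that("a fully surrounded leader extends no lamellipodium", {
  cfg <- sim_config(zeta_lamellipodia = 50)
  st <- build_substrate(c(9, 9, 6))
  st$owner[, , 2:5] <- 2L       # follower shell fills the slab
  st$owner[4:6, 4:6, 2:3] <- 1L # leader buried inside
  st$cell_type <- c("leader", "follower")
  expect_equal(nrow(free_edge_voxels(st, 1)), 0)
  set.seed(2)
  st2 <- cycle_lamellipodium(st, cfg, 1)
  expect_equal(sum(st2$links$kind == "lamellipodium"), 0)
})

test_that("follower-substrate links require contact and re-anchor on firing", {
  cfg <- sim_config(zeta_substrate = 50)
  st <- build_substrate(c(20, 20, 12))
  st$owner[5:9, 5:9, 2:6] <- 1L    # bottom follower
  st$owner[5:9, 5:9, 7:11] <- 2L   # top follower, no substrate contact
  st$cell_type <- c("follower", "follower")
  set.seed(3)
  st2 <- cycle_follower_substrate(st, cfg, 2)
  expect_equal(nrow(st2$links), 0)  # top layer holds no substrate link

  st2 <- cycle_follower_substrate(st, cfg, 1)
  lk <- st2$links
  expect_equal(lk$kind, "follower_substrate")
  expect_equal(c(lk$anchor_x, lk$anchor_y, lk$anchor_z), c(7, 7, 1))

  # zeta = 0: anchor never moves even if the centroid does
  cfg0 <- update_config(cfg, zeta_substrate = 0)
  st3 <- st2
  st3$owner[5:9, 5:9, 2:6] <- 0L
  st3$owner[8:12, 8:12, 2:6] <- 1L
  st4 <- cycle_follower_substrate(st3, cfg0, 1)
  expect_equal(st4$links$anchor_x, 7)
  # firing re-anchors beneath the new centroid
  st5 <- cycle_follower_substrate(st3, cfg, 1)
  expect_equal(c(st5$links$anchor_x, st5$links$anchor_y), c(10, 10))
})
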
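test_that("total energy reproduces hand-computed single-cell cases", {
  cfg <- sim_config(contact_energy = matrix(0, 4, 4), lambda_volume = 2,
                    v_target = 8)
  st <- build_substrate(c(8, 8, 6))
  st$owner[3:4, 3:4, 3:4] <- 1L  # 2x2x2 cell, exactly v_target
  st$cell_type <- "follower"
  expect_equal(compute_total_energy(st, cfg), 0)

  st$owner[5, 3, 3] <- 1L        # one voxel over target
  expect_equal(compute_total_energy(st, cfg), 2) # lambda * 1^2
})

test_that("total energy matches a term-by-term brute-force oracle", {
  for (seed in 1:4) {
    st <- random_test_state(seed)
    cfg <- random_test_config(seed)
    expect_equal(compute_total_energy(st, cfg), bf_total_energy(st, cfg),
                 tolerance = 1e-12)
  }
})

test_that("incremental delta-H equals a full recompute on random attempts", {
  n_checked <- 0
  for (seed in 1:4) {
    st <- random_test_state(seed)
    cfg <- random_test_config(seed)
    dm <- dim(st$owner)
    set.seed(seed + 50)
    H0 <- bf_total_energy(st, cfg)
    tries <- 0
    while (n_checked < seed * 25 && tries < 3000) {
      tries <- tries + 1
      tgt <- c(sample(dm[1], 1), sample(dm[2], 1), sample(2:dm[3], 1))
      off <- diag(3)[sample(3, 1), ] * sample(c(-1, 1), 1)
      src <- tgt + off
      if (any(src < 1) || any(src > dm) || src[3] < 2) next
      if (st$owner[src[1], src[2], src[3]] == st$owner[tgt[1], tgt[2], tgt[3]]) next
      dh <- delta_energy(st, cfg, src, tgt)
      after <- bf_apply_copy(st, src, tgt)
      expect_equal(dh, bf_total_energy(after, cfg) - H0, tolerance = 1e-9)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 100)
})

test_that("delta-H rejects substrate involvement and same-owner pairs", {
  st <- random_test_state(1)
  cfg <- random_test_config(1)
  expect_error(delta_energy(st, cfg, c(1, 1, 1), c(1, 1, 2)), "substrate")
  same <- which(st$owner[, , 2] == st$owner[, , 3], arr.ind = TRUE)[1, ]
  expect_error(delta_energy(st, cfg, c(same[1], same[2], 2),
                            c(same[1], same[2], 3)), "same owner")
})

test_that("acceptance probability follows the Boltzmann rule", {
  expect_equal(acceptance_probability(-3, 10), 1)
  expect_equal(acceptance_probability(0, 10), 1)
  T <- 7.3
  expect_equal(acceptance_probability(T, T), exp(-1))
  expect_equal(acceptance_probability(c(-1, 0, 2), 4),
               c(1, 1, exp(-0.5)))
  expect_error(acceptance_probability(1, 0), "temperature")
})

test_that("a Monte-Carlo step is deterministic under a fixed seed", {
  cfg <- sim_config()
  st <- two_cell_state(cfg)
  a <- run_cpm(st, cfg, n_mcs = 20, seed = 42, sample_every = 0)
  b <- run_cpm(st, cfg, n_mcs = 20, seed = 42, sample_every = 0)
  expect_identical(a$state$owner, b$state$owner)
  expect_identical(a$state$links, b$state$links)
  c_ <- run_cpm(st, cfg, n_mcs = 20, seed = 43, sample_every = 0)
  expect_false(identical(a$state$owner, c_$state$owner))
})

test_that("substrate plane is immutable and lattice content conserved", {
  cfg <- sim_config()
  st <- two_cell_state(cfg)
  run <- run_cpm(st, cfg, n_mcs = 30, seed = 7, sample_every = 0)
  own <- run$state$owner
  expect_true(all(own[, , 1] == -1L))
  expect_true(all(own[, , -1] != -1L))
  expect_identical(dim(own), dim(st$owner))
})

test_that("near-zero temperature freezes a relaxed configuration", {
  cfg <- sim_config(contact_energy = matrix(0, 4, 4), temperature = 1e-6,
                    v_target = 125, zeta_lamellipodia = 0, zeta_substrate = 0)
  st <- two_cell_state(cfg)
  st$links <- empty_links()
  run <- run_cpm(st, cfg, n_mcs = 5, seed = 3, sample_every = 0)
  expect_identical(run$state$owner, st$owner)
})

test_that("volumes stay near target over a short run at defaults", {
  cfg <- sim_config()
  st <- two_cell_state(cfg)
  run <- run_cpm(st, cfg, n_mcs = 50, seed = 11, sample_every = 0)
  expect_true(all(abs(run$volumes - cfg$v_target) <= 0.3 * cfg$v_target))
})

test_that("two identical cells keep statistically equal volumes", {
  cfg <- sim_config(zeta_lamellipodia = 0, zeta_substrate = 0)
  st <- two_cell_state(cfg)
  st$links <- empty_links()
  d <- vapply(1:10, function(s) {
    run <- run_cpm(st, cfg, n_mcs = 60, seed = s, sample_every = 0)
    run$volumes[1] - run$volumes[2]
  }, numeric(1))
  se <- sd(d) / sqrt(length(d))
  expect_lte(abs(mean(d)), 3 * se + 1e-9)
})
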
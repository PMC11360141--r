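test_that("unit conversion obeys 1 voxel/MCS = 4320 um/h", {
  cfg <- sim_config()
  expect_equal(voxels_per_mcs_to_um_per_h(1, cfg), 4320)
  expect_equal(voxels_per_mcs_to_um_per_h(0.5, cfg), 2160)
})

test_that("DMZ migration speed converts synthetic drift correctly", {
  cfg <- sim_config()
  still <- synth_trajectory(n_cells = 4, n_samples = 8, drift = 0)
  expect_equal(dmz_migration_speed(still, cfg, 1:4), 0)
  # 1 voxel per 200 MCS = 6 um / 1000 s = 21.6 um/h
  tr <- synth_trajectory(n_cells = 4, n_samples = 8, drift = 1)
  expect_equal(dmz_migration_speed(tr, cfg, 1:4), 21.6)
  tr2 <- synth_trajectory(n_cells = 4, n_samples = 8, drift = 2)
  expect_equal(dmz_migration_speed(tr2, cfg, 1:4),
               2 * dmz_migration_speed(tr, cfg, 1:4))
  # signed along the axis, and axis-aware
  back <- synth_trajectory(drift = -1)
  expect_equal(dmz_migration_speed(back, cfg, 1:4), -21.6)
  expect_equal(dmz_migration_speed(back, cfg, 1:4, axis = c(0, -1, 0)), 21.6)
  one <- synth_trajectory(n_samples = 1)
  expect_error(dmz_migration_speed(one, cfg, 1:4), "2")
})

test_that("net and path-length speed variants differ for wiggly tracks", {
  cfg <- sim_config()
  tr <- synth_trajectory(n_cells = 1, n_samples = 5, drift = 0)
  tr$y <- c(0, 2, 0, 2, 0)  # oscillating: zero net, nonzero path
  expect_equal(dmz_migration_speed(tr, cfg, 1), 0)
  expect_gt(dmz_migration_speed(tr, cfg, 1, method = "path"), 0)
})

test_that("ITR closure speed equals the regression on the side length", {
  cfg <- sim_config()
  ar <- synth_area_record(side0 = 40, rate = 2, n_samples = 8)
  cs <- itr_closure_speed(ar, cfg)
  expect_equal(cs$speed, 2 / 200 * 4320)  # 2 voxels per 200-MCS sample
  expect_equal(cs$per_edge, cs$speed / 2)
  flat <- synth_area_record(side0 = 30, rate = 0, n_samples = 6)
  expect_equal(itr_closure_speed(flat, cfg)$speed, 0)
  closed <- synth_area_record(side0 = 0, rate = 0, n_samples = 4)
  expect_error(itr_closure_speed(closed, cfg), "closed")
  # quadratic closure against the closed-form least-squares slope
  s <- 1:8
  side <- 40 - 0.5 * (s - 1)^2
  ar2 <- data.frame(sample = s, mcs = (s - 1) * 200, free_area = side^2)
  x <- ar2$mcs; y <- side
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(itr_closure_speed(ar2, cfg)$speed, abs(beta) * 4320,
               tolerance = 1e-12)
})

test_that("retraction distance is the mean rearward displacement in um", {
  cfg <- sim_config()
  tr <- synth_trajectory(n_cells = 8, n_samples = 4, drift = 0)
  expect_equal(retraction_distance(tr, cfg, 1:8), 0)
  tr$y <- tr$y - (tr$sample - 1) / 3 * 2  # uniform 2-voxel rearward shift
  expect_equal(retraction_distance(tr, cfg, 1:8), 12)
  fw <- synth_trajectory(n_cells = 8, n_samples = 4, drift = 1)
  expect_lt(retraction_distance(fw, cfg, 1:8), 0)
})

test_that("Student's t-test matches the base-R reference implementation", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  ours <- t_test_independent(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  set.seed(30)
  x <- rnorm(12); y <- rnorm(9, 0.8)
  ours2 <- t_test_independent(x, y)
  ref2 <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours2$t, unname(ref2$statistic), tolerance = 1e-10)
  expect_equal(ours2$p, ref2$p.value, tolerance = 1e-10)
  # symmetry and degeneracy
  sw <- t_test_independent(y, x)
  expect_equal(sw$t, -ours2$t)
  expect_equal(sw$p, ours2$p)
  same <- t_test_independent(c(2, 2, 2), c(2, 2, 2))
  expect_equal(c(same$t, same$p), c(0, 1))
  expect_error(t_test_independent(1, c(1, 2)), "n >= 2")
})

test_that("one-way ANOVA matches the base-R reference implementation", {
  g <- list(c(1, 2, 3, 4), c(2, 3, 4, 6), c(5, 5, 6, 7))
  ours <- one_way_anova(g)
  dat <- data.frame(y = unlist(g), grp = factor(rep(1:3, lengths(g))))
  ref <- oneway.test(y ~ grp, dat, var.equal = TRUE)
  expect_equal(ours$F, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  ident <- one_way_anova(list(c(1, 1), c(1, 1)))
  expect_equal(c(ident$F, ident$p), c(0, 1))
  expect_error(one_way_anova(list(1:3)), "2 groups")
  # permuting labels of exchangeable data rarely yields significance
  set.seed(31)
  y <- rnorm(30)
  ps <- vapply(1:100, function(i) {
    grp <- sample(rep(1:3, each = 10))
    one_way_anova(split(y, grp))$p
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.15)
})

test_that("sensitivity slope is the least-squares slope", {
  lv <- seq(-0.5, 0.5, 0.25)
  expect_equal(sensitivity_slope(lv, rep(3, 5)), 0)
  expect_equal(sensitivity_slope(lv, 1 + 2 * lv), 2)
  set.seed(32)
  y <- 4 * lv + rnorm(5, 0, 0.1)
  beta <- sum((lv - mean(lv)) * (y - mean(y))) / sum((lv - mean(lv))^2)
  expect_equal(sensitivity_slope(lv, y), beta, tolerance = 1e-12)
  expect_error(sensitivity_slope(c(0, 1), c(1, 2)), "3 levels")
})

test_that("metrics are pure functions of recorded data", {
  cfg <- sim_config()
  set.seed(33)
  tr <- synth_trajectory(noise_sd = 0.3)
  expect_identical(dmz_migration_speed(tr, cfg, 1:4),
                   dmz_migration_speed(tr, cfg, 1:4))
  ar <- synth_area_record(noise_sd = 0.5)
  expect_identical(itr_closure_speed(ar, cfg), itr_closure_speed(ar, cfg))
})
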
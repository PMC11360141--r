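cc_link_counts <- function(links, ids) {
  vapply(ids, function(id)
    sum(links$kind == "cell_cell" & (links$a == id | links$b == id)), numeric(1))
}

test_that("cell-cell links break at the closed-form Poisson rate", {
  lk <- empty_links()
  for (i in 1:2000) lk <- rbind(lk, data.frame(
    kind = "cell_cell", a = 1L, b = 2L, anchor_x = NA_real_, anchor_y = NA_real_,
    anchor_z = NA_real_, lambda = 1, target_length = 5, age = 0L,
    satisfied = FALSE))
  expect_length(maybe_break_cell_links(lk, 0), 0)
  set.seed(20)
  zeta <- 0.1
  p <- 1 - exp(-zeta)
  n_broken <- sum(vapply(1:50, function(i) length(maybe_break_cell_links(lk, zeta)),
                         numeric(1)))
  n_total <- 50 * nrow(lk)
  expect_lt(abs(n_broken - n_total * p), 3 * sqrt(n_total * p * (1 - p)))
  expect_error(maybe_break_cell_links(lk, -0.1), ">= 0")
})

test_that("reformation respects the neighbor cap on both endpoints", {
  mk <- function(a, b) data.frame(kind = "cell_cell", a = a, b = b,
                                  anchor_x = NA_real_, anchor_y = NA_real_,
                                  anchor_z = NA_real_, lambda = 1,
                                  target_length = 5, age = 0L, satisfied = FALSE)
  links <- rbind(mk(1, 2), mk(1, 3), mk(1, 4), mk(1, 5))
  # cell 1 already at the cap of 4: no new link
  expect_identical(reform_link(links, 1, c(6, 7), 4, 1, 5), links)
  # no candidates: unchanged
  expect_identical(reform_link(links, 2, integer(0), 4, 1, 5), links)
  # exactly one eligible neighbor: deterministic link
  set.seed(1)
  out <- reform_link(links, 2, c(6), 4, 1, 5)
  expect_equal(nrow(out), 5)
  expect_setequal(unlist(out[5, c("a", "b")]), c(2, 6))
  # a saturated partner is not eligible
  out2 <- reform_link(links, 6, c(1), 4, 1, 5)
  expect_identical(out2, links)
  # already-linked partners are not eligible
  out3 <- reform_link(links, 2, c(1), 4, 1, 5)
  expect_identical(out3, links)
})

test_that("zero tissue turnover leaves the link set invariant", {
  cfg <- sim_config(zeta_tissue = 0)
  st <- dmz_state(cfg, seed = 1, preset = "reduced")
  set.seed(2)
  st2 <- intercalation_step(st, cfg)
  expect_identical(st2$links, st$links)
  # and through the engine over a time horizon (modulo ages/anchors/satisfied)
  run <- run_cpm(st, cfg, n_mcs = 15, seed = 2, sample_every = 0)
  key <- function(l) {
    l <- l[l$kind == "cell_cell", c("a", "b")]
    l[order(l$a, l$b), ]
  }
  expect_equal(unname(key(run$state$links)), unname(key(st$links)))
})

test_that("intercalation turnover never pushes a cell past the cap", {
  cfg <- sim_config(zeta_tissue = 0.3)  # aggressive turnover
  st <- dmz_state(cfg, seed = 3, preset = "reduced")
  ids <- seq_along(st$cell_type)
  init <- cc_link_counts(st$links, ids)
  # R-level step applied repeatedly
  set.seed(3)
  st2 <- st
  for (i in 1:10) st2 <- intercalation_step(st2, cfg)
  after <- cc_link_counts(st2$links, ids)
  expect_true(all(after <= pmax(init, cfg$max_reformed_neighbors)))
  # engine path over a longer horizon
  run <- run_cpm(st, cfg, n_mcs = 40, seed = 3, sample_every = 0)
  after_engine <- cc_link_counts(run$state$links, ids)
  expect_true(all(after_engine <= pmax(init, cfg$max_reformed_neighbors)))
  expect_gt(run$n_breaks, 0)
  expect_gt(run$n_reforms, 0)
})

test_that("broken links are reformed to lattice-adjacent unlinked cells only", {
  cfg <- sim_config(zeta_tissue = 5)  # essentially every link breaks
  st <- dmz_state(cfg, seed = 4, preset = "reduced")
  set.seed(4)
  st2 <- intercalation_step(st, cfg)
  new_rows <- st2$links[st2$links$age == 0 & st2$links$kind == "cell_cell", ]
  for (i in seq_len(nrow(new_rows))) {
    nb <- adjacent_cells(st2, new_rows$a[i])
    expect_true(new_rows$b[i] %in% nb)
  }
})
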
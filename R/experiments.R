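#' Replicate seeds
#'
#' Deterministic per-replicate seeds `base_seed + i`, logged with every
#' experiment so any replicate replays bit-identically.
#'
#' @param base_seed integer base seed.
#' @param n number of replicates.
#' @return integer vector of length `n`.
#' @export
replicate_seeds <- function(base_seed, n) as.integer(base_seed) + seq_len(n)

#' Run one DMZ replicate and measure its migration speed
#'
#' Builds a single-explant state seeded with `seed`, runs `n_mcs` steps and
#' returns the migration speed of the center four leading-row cells.
#'
#' @param config a `sim_config`.
#' @param seed replicate seed (initial lamellipodium directions and the
#'   engine stream).
#' @param n_mcs run length (default 1440 MCS = 2 h).
#' @param preset lattice preset, see [dmz_state()].
#' @param keep_run return the full `cpm_run` alongside the speed.
#' @return list with `speed` (um/h), `seed`, and optionally `run`.
#' @export
run_dmz_replicate <- function(config, seed, n_mcs = 1440, preset = "standard",
                              keep_run = FALSE) {
  state <- dmz_state(config, seed = seed, preset = preset)
  run <- run_cpm(state, config, n_mcs = n_mcs, seed = seed)
  ex <- state$meta$explants[[1]]
  speed <- dmz_migration_speed(run$trajectory, config, ex$center4, ex$axis)
  out <- list(speed = speed, seed = seed)
  if (keep_run) out$run <- run
  out
}

#' Run one ITR replicate and measure its closure speed
#'
#' Builds the four-explant state, runs up to `n_mcs` steps (stopping at gap
#' closure), and measures the closure speed from the free-area side length.
#'
#' @inheritParams run_dmz_replicate
#' @param sample_every free-area sampling interval in MCS; gap closure can
#'   complete within a few hundred MCS, so the area series is sampled more
#'   finely than the 200-MCS trajectory cadence.
#' @return list with `speed` (um/h, side-length rate), `per_edge`, `closed`,
#'   `seed`, `substrate_cells` (per-sample counts) and optionally `run`.
#' @export
run_itr_replicate <- function(config, seed, n_mcs = 1440, preset = "standard",
                              sample_every = 50, keep_run = FALSE) {
  state <- itr_state(config, seed = seed, preset = preset)
  gap <- state$meta$gap
  gap_area <- (gap[2] - gap[1] + 1) * (gap[4] - gap[3] + 1)
  run <- run_cpm(state, config, n_mcs = n_mcs, seed = seed,
                 sample_every = sample_every,
                 gap = gap, stop_when_closed = TRUE,
                 close_threshold = floor(0.05 * gap_area))
  cs <- itr_closure_speed(run$series, config)
  out <- list(speed = cs$speed, per_edge = cs$per_edge, closed = run$closed,
              seed = seed, substrate_cells = run$series$substrate_cells)
  if (keep_run) out$run <- run
  out
}

#' Cohesotaxis (kappa) sweep
#'
#' Runs `n_reps` seeded replicates per kappa level in the chosen geometry and
#' summarizes the effect of migratory bias on speed: pairwise Student's
#' t-tests for the single DMZ explant, a one-way ANOVA across levels for the
#' ITR configuration.
#'
#' @param config a `sim_config`.
#' @param kappas kappa levels in `[-6, 6]`.
#' @param geometry `"dmz"` or `"itr"`.
#' @param n_reps replicates per level.
#' @param seed base seed; replicate seeds are `seed + i`, advanced per level.
#' @param n_mcs run length per replicate.
#' @param preset lattice preset.
#' @return list of class `experiment_result`: `results` (kappa, rep, seed,
#'   speed, closed), `stats` (pairwise t-tests or ANOVA), `geometry`.
#' @export
run_kappa_sweep <- function(config, kappas = c(-6, 0, 6),
                            geometry = c("dmz", "itr"), n_reps = 10,
                            seed = config$seed, n_mcs = 1440,
                            preset = "standard") {
  geometry <- match.arg(geometry)
  if (any(kappas < -6 | kappas > 6)) stop("kappa must be in [-6, 6]")
  rows <- list()
  counter <- 0
  for (kap in kappas) {
    cfg <- update_config(config, kappa = kap)
    for (i in seq_len(n_reps)) {
      counter <- counter + 1
      s <- as.integer(seed) + counter
      rep_res <- if (geometry == "dmz")
        run_dmz_replicate(cfg, s, n_mcs, preset)
      else run_itr_replicate(cfg, s, n_mcs, preset)
      rows[[counter]] <- data.frame(kappa = kap, rep = i, seed = s,
                                    speed = rep_res$speed,
                                    closed = if (geometry == "itr") rep_res$closed else NA)
    }
  }
  results <- do.call(rbind, rows)
  groups <- split(results$speed, results$kappa)
  stats <- if (geometry == "dmz") {
    prs <- utils::combn(as.character(kappas), 2)
    do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
      tt <- t_test_independent(groups[[prs[1, j]]], groups[[prs[2, j]]])
      data.frame(kappa_a = as.numeric(prs[1, j]), kappa_b = as.numeric(prs[2, j]),
                 t = tt$t, p = tt$p)
    }))
  } else {
    av <- one_way_anova(groups)
    data.frame(F = av$F, p = av$p, df1 = av$df1, df2 = av$df2)
  }
  structure(list(results = results, stats = stats, geometry = geometry,
                 kappas = kappas, n_reps = n_reps, base_seed = seed),
            class = "experiment_result")
}

#' ITR closure experiment over intercalation rates
#'
#' Runs ITR replicates per `zeta_tissue` level, returning closure speeds,
#' substrate-cell-count time series, the t-test of the largest level against
#' `zeta_tissue = 0` (intercalation disabled), and the rank correlation of
#' speed with level across the positive levels.
#'
#' @param config a `sim_config`.
#' @param zeta_values `zeta_tissue` levels; include 0 for the disabled arm.
#' @param n_reps replicates per level (scalar, or one value per level).
#' @param seed base seed.
#' @param n_mcs run length cap per replicate.
#' @param preset lattice preset.
#' @return `experiment_result` with `results` (zeta_tissue, rep, seed, speed,
#'   closed), `substrate_series`, and `stats` (`t_vs_disabled`,
#'   `rank_correlation`).
#' @export
run_itr_closure <- function(config, zeta_values = c(0, 1e-4, 1e-3, 1e-2, 0.1),
                            n_reps = 10, seed = config$seed, n_mcs = 1440,
                            preset = "standard") {
  n_reps <- rep(n_reps, length.out = length(zeta_values))
  rows <- list()
  sub_rows <- list()
  counter <- 0
  for (li in seq_along(zeta_values)) {
    zt <- zeta_values[li]
    cfg <- update_config(config, zeta_tissue = zt)
    for (i in seq_len(n_reps[li])) {
      counter <- counter + 1
      s <- as.integer(seed) + counter
      r <- run_itr_replicate(cfg, s, n_mcs, preset)
      rows[[counter]] <- data.frame(zeta_tissue = zt, rep = i, seed = s,
                                    speed = r$speed, closed = r$closed)
      sub_rows[[counter]] <- data.frame(zeta_tissue = zt, rep = i,
                                        sample = seq_along(r$substrate_cells),
                                        substrate_cells = r$substrate_cells)
    }
  }
  results <- do.call(rbind, rows)
  stats <- list()
  zmax <- max(zeta_values)
  if (0 %in% zeta_values && zmax > 0) {
    tt <- t_test_independent(results$speed[results$zeta_tissue == zmax],
                             results$speed[results$zeta_tissue == 0])
    stats$t_vs_disabled <- data.frame(zeta = zmax, t = tt$t, p = tt$p)
  }
  pos <- results[results$zeta_tissue > 0, ]
  if (length(unique(pos$zeta_tissue)) >= 3) {
    ct <- cor.test(rank(pos$zeta_tissue), pos$speed, method = "spearman",
                   exact = FALSE)
    stats$rank_correlation <- data.frame(rho = unname(ct$estimate), p = ct$p.value)
  }
  structure(list(results = results,
                 substrate_series = do.call(rbind, sub_rows),
                 stats = stats, zeta_values = zeta_values, base_seed = seed),
            class = "experiment_result")
}

sensitivity_params <- c("lambda_lamellipodia", "lambda_tissue", "chi_lamellipodia",
                        "lambda_follower_substrate", "zeta_lamellipodia",
                        "zeta_substrate")

#' One-dimensional parameter sensitivity sweep
#'
#' Varies each migratory parameter one at a time by the given fractional
#' levels around the calibrated baseline (baseline level 0 included once per
#' parameter), with `n_reps` seeded DMZ replicates per level. Reports
#' per-level speeds, a one-way ANOVA across levels per parameter, and the
#' regression slope of mean speed versus fractional change
#' ([sensitivity_slope()]).
#'
#' @param config a `sim_config` (the baseline).
#' @param params parameters to vary (subset of the six migratory parameters).
#' @param levels fractional changes, e.g. `seq(-0.5, 0.5, 0.1)`; 0 is the
#'   baseline and must lie strictly above -1.
#' @param n_reps replicates per level.
#' @param seed base seed; replicate seeds advance across the whole design so
#'   each level draws fresh seeds.
#' @param n_mcs run length per replicate.
#' @param preset lattice preset.
#' @return `experiment_result` with `results` (param, level, rep, seed,
#'   speed) and `stats` (param, anova_F, anova_p, slope, abs_slope).
#' @export
run_sensitivity <- function(config, params = sensitivity_params,
                            levels = seq(-0.5, 0.5, 0.1), n_reps = 10,
                            seed = config$seed, n_mcs = 1440,
                            preset = "standard") {
  stopifnot(all(params %in% sensitivity_params))
  if (any(levels <= -1)) stop("fractional levels must be > -1")
  levels <- sort(unique(round(levels, 10)))
  rows <- list()
  counter <- 0
  for (par in params) {
    for (lv in levels) {
      cfg <- config
      cfg[[par]] <- config[[par]] * (1 + lv)
      cfg <- validate_sim_config(cfg)
      for (i in seq_len(n_reps)) {
        counter <- counter + 1
        s <- as.integer(seed) + counter
        r <- run_dmz_replicate(cfg, s, n_mcs, preset)
        rows[[counter]] <- data.frame(param = par, level = lv, rep = i,
                                      seed = s, speed = r$speed)
      }
    }
  }
  results <- do.call(rbind, rows)
  stats <- do.call(rbind, lapply(params, function(par) {
    d <- results[results$param == par, ]
    av <- one_way_anova(split(d$speed, d$level))
    means <- vapply(split(d$speed, d$level), mean, numeric(1))
    sl <- sensitivity_slope(as.numeric(names(means)), means)
    data.frame(param = par, anova_F = av$F, anova_p = av$p,
               slope = sl, abs_slope = abs(sl))
  }))
  stats <- stats[order(-stats$abs_slope), ]
  structure(list(results = results, stats = stats, levels = levels,
                 n_reps = n_reps, base_seed = seed),
            class = "experiment_result")
}

#' Lamellipodia-blocking retraction experiment
#'
#' Each replicate migrates for `pre_mcs` steps (about 17 min) to reach a
#' migratory steady state; formation of new lamellipodium links is then
#' blocked while existing links expire through their Poisson lifetime, and
#' the run continues for `post_mcs` steps. The retraction distance is the
#' mean rearward displacement of the leading-row cells from block onset to
#' the end. Unblocked control replicates are measured identically.
#'
#' @param config a `sim_config`.
#' @param n_reps replicates per arm.
#' @param seed base seed.
#' @param pre_mcs steps before block onset.
#' @param post_mcs steps after block onset.
#' @param preset lattice preset.
#' @return `experiment_result` with `results` (arm, rep, seed, retraction_um,
#'   lam_links_final) and `stats` (mean +/- sem per arm).
#' @export
run_retraction_validation <- function(config, n_reps = 10, seed = config$seed,
                                      pre_mcs = 200, post_mcs = 600,
                                      preset = "standard") {
  blocked_cfg <- update_config(config, lamellipodia_blocked = TRUE)
  rows <- list()
  counter <- 0
  for (arm in c("blocked", "control")) {
    for (i in seq_len(n_reps)) {
      counter <- counter + 1
      s <- as.integer(seed) + i  # same seeds in both arms: paired perturbation
      state <- dmz_state(config, seed = s, preset = preset)
      ex <- state$meta$explants[[1]]
      pre <- run_cpm(state, config, n_mcs = pre_mcs, seed = s)
      cfg2 <- if (arm == "blocked") blocked_cfg else config
      post <- run_cpm(pre$state, cfg2, n_mcs = post_mcs, seed = s + 7919L)
      ret <- retraction_distance(post$trajectory, config,
                                 ex$leading_row_bottom, ex$axis)
      rows[[counter]] <- data.frame(arm = arm, rep = i, seed = s,
                                    retraction_um = ret,
                                    lam_links_final = post$series$n_lamellipodium[nrow(post$series)])
    }
  }
  results <- do.call(rbind, rows)
  stats <- do.call(rbind, lapply(split(results, results$arm), function(d) {
    data.frame(arm = d$arm[1], mean = mean(d$retraction_um),
               sem = sd(d$retraction_um) / sqrt(nrow(d)))
  }))
  structure(list(results = results, stats = stats, base_seed = seed),
            class = "experiment_result")
}

#' Calibration gates for the shipped defaults
#'
#' Re-checks, over a few seeded DMZ replicates, the qualitative behaviors the
#' default parameterization was calibrated to: (1) no explant fragmentation
#' (every cell one connected component at the end of the run), (2) cell
#' volumes within +/-30% of `v_target`, (3) persistent forward leading-edge
#' displacement (Spearman correlation of mean leading-row position with time
#' >= 0.9 and positive net displacement), and (4) migration speed inside the
#' 50-200 um/h band around the biological reference.
#'
#' @param config a `sim_config`.
#' @param n_seeds number of replicates.
#' @param seed base seed.
#' @param n_mcs run length.
#' @param preset lattice preset.
#' @return data.frame, one row per replicate, with per-gate logicals, speed,
#'   and an overall `pass`.
#' @export
calibration_gates <- function(config, n_seeds = 5, seed = config$seed,
                              n_mcs = 1440, preset = "standard") {
  rows <- lapply(replicate_seeds(seed, n_seeds), function(s) {
    state <- dmz_state(config, seed = s, preset = preset)
    ex <- state$meta$explants[[1]]
    run <- run_cpm(state, config, n_mcs = n_mcs, seed = s)
    comp <- cell_component_counts(run$state)
    frag_ok <- all(comp[run$alive] == 1)
    vol_ok <- all(abs(run$volumes[run$alive] - config$v_target) <=
                    0.3 * config$v_target)
    tr <- run$trajectory[run$trajectory$cell %in% ex$leading_row_bottom, ]
    pos <- tapply(tr$x * ex$axis[1] + tr$y * ex$axis[2], tr$sample, mean)
    mono_ok <- suppressWarnings(stats::cor(seq_along(pos), pos,
                                           method = "spearman")) >= 0.9 &&
      pos[length(pos)] > pos[1]
    speed <- dmz_migration_speed(run$trajectory, config, ex$center4, ex$axis)
    speed_ok <- speed >= 50 && speed <= 200
    data.frame(seed = s, fragmentation_ok = frag_ok, volume_ok = vol_ok,
               monotone_ok = mono_ok, speed = speed, speed_ok = speed_ok,
               pass = frag_ok && vol_ok && mono_ok && speed_ok)
  })
  do.call(rbind, rows)
}

#' Search for a parameterization satisfying the calibration gates
#'
#' Grid search over named parameter vectors: each combination is scored with
#' [calibration_gates()] and the first fully passing configuration is
#' returned (with the gate table); if none passes, the nearest miss (most
#' gates passed) is returned with diagnostics.
#'
#' @param base_config starting `sim_config`.
#' @param grid named list of candidate value vectors for config fields.
#' @param n_seeds replicates per candidate.
#' @param seed base seed.
#' @param n_mcs run length per replicate.
#' @param preset lattice preset.
#' @return list with `config`, `gates`, `passed`, `n_evaluated`.
#' @export
calibrate_defaults <- function(base_config, grid = list(), n_seeds = 3,
                               seed = base_config$seed, n_mcs = 720,
                               preset = "reduced") {
  combos <- if (length(grid)) expand.grid(grid, stringsAsFactors = FALSE)
             else data.frame(row.names = 1)
  best <- NULL; best_score <- -1
  for (i in seq_len(nrow(combos))) {
    cfg <- base_config
    for (nm in names(combos)) cfg[[nm]] <- combos[[nm]][i]
    cfg <- validate_sim_config(cfg)
    gates <- calibration_gates(cfg, n_seeds = n_seeds, seed = seed,
                               n_mcs = n_mcs, preset = preset)
    score <- sum(gates$fragmentation_ok) + sum(gates$volume_ok) +
      sum(gates$monotone_ok) + sum(gates$speed_ok)
    if (all(gates$pass))
      return(list(config = cfg, gates = gates, passed = TRUE, n_evaluated = i))
    if (score > best_score) { best <- list(config = cfg, gates = gates); best_score <- score }
  }
  c(best, list(passed = FALSE, n_evaluated = nrow(combos)))
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>", nrow(x$results), "replicate rows\n")
  if (!is.null(x$stats)) { cat("stats:\n"); print(x$stats) }
  invisible(x)
}
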
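#' Unit conversion: voxels per MCS to microns per hour
#'
#' 1 voxel/MCS = 6 um / 5 s = 4320 um/h under the default calibration.
#'
#' @param v speed in voxels per MCS.
#' @param config a `sim_config` (supplies `microns_per_voxel`,
#'   `seconds_per_mcs`).
#' @return speed in um/h.
#' @export
voxels_per_mcs_to_um_per_h <- function(v, config) {
  v * config$microns_per_voxel / config$seconds_per_mcs * 3600
}

#' DMZ migration speed
#'
#' Mean over the tracked cells (by default the center four leading-row
#' cells) of the net displacement along the migration axis divided by the
#' elapsed time, in um/h. The 2-h protocol runs 1440 MCS with centroids
#' sampled every 200 MCS.
#'
#' @param trajectory data.frame with columns sample, mcs, cell, x, y, z as
#'   produced by [run_cpm()] (or [synth_trajectory()]).
#' @param config a `sim_config`.
#' @param cell_ids cells to average over.
#' @param axis numeric length-3 migration direction (unit vector).
#' @param method `"net"` (net displacement, default) or `"path"` (summed
#'   per-sample path length along the axis).
#' @return speed in um/h (signed along `axis` for `"net"`).
#' @export
dmz_migration_speed <- function(trajectory, config, cell_ids,
                                axis = c(0, 1, 0), method = c("net", "path")) {
  method <- match.arg(method)
  tr <- trajectory[trajectory$cell %in% cell_ids, , drop = FALSE]
  if (length(unique(tr$sample)) < 2) stop("need at least 2 trajectory samples")
  proj <- tr$x * axis[1] + tr$y * axis[2] + tr$z * axis[3]
  per_cell <- vapply(split(data.frame(mcs = tr$mcs, p = proj), tr$cell),
                     function(d) {
                       d <- d[order(d$mcs), ]
                       dp <- if (method == "net") d$p[nrow(d)] - d$p[1]
                             else sum(abs(diff(d$p)))
                       dt <- d$mcs[nrow(d)] - d$mcs[1]
                       dp / dt
                     }, numeric(1))
  voxels_per_mcs_to_um_per_h(mean(per_cell), config)
}

#' ITR gap-closure speed
#'
#' The free area of the central gap is tracked as its equivalent side length
#' `side(t) = sqrt(free_area(t))`; the closure speed is the absolute slope of
#' the least-squares line of side versus time over the closing phase
#' (samples with positive free area), converted to um/h. Because two
#' opposing leading edges advance simultaneously, the per-edge advance is
#' half the side-length rate; both are reported.
#'
#' @param area_record data.frame with columns mcs and free_area as produced
#'   by [run_cpm()]'s `series` (or [synth_area_record()]).
#' @param config a `sim_config`.
#' @param closed_fraction fraction of the initial area below which the gap
#'   counts as effectively closed; the seam between collided explant edges
#'   retains a few medium columns indefinitely, and including that plateau in
#'   the fit would dilute the closing-phase slope.
#' @return list with `speed` (um/h, side-length rate), `per_edge`
#'   (`speed / 2`), `slope` (voxels/MCS, signed) and `n_samples` used.
#' @export
itr_closure_speed <- function(area_record, config, closed_fraction = 0.05) {
  ar <- area_record[!is.na(area_record$free_area), , drop = FALSE]
  if (all(ar$free_area == 0)) stop("gap already closed in every sample")
  thr <- closed_fraction * max(ar$free_area)
  below <- which(ar$free_area <= thr)
  if (length(below)) ar <- ar[seq_len(min(below)), , drop = FALSE]
  closing <- ar[ar$free_area > 0, , drop = FALSE]
  if (nrow(closing) < 3) stop("need at least 3 samples in the closing phase")
  side <- sqrt(closing$free_area)
  slope <- unname(coef(lm(side ~ closing$mcs))[2])
  speed <- voxels_per_mcs_to_um_per_h(abs(slope), config)
  list(speed = speed, per_edge = speed / 2, slope = slope,
       n_samples = nrow(closing))
}

#' Retraction distance after lamellipodia blocking
#'
#' Mean rearward displacement of the leading-row cells along the migration
#' axis from block onset to the final sample, in um. Forward motion after the
#' block yields a negative value.
#'
#' @param trajectory trajectory data.frame covering block onset to steady
#'   state.
#' @param config a `sim_config`.
#' @param cell_ids leading-row cells to average over.
#' @param axis migration axis (unit vector).
#' @return retraction distance in um.
#' @export
retraction_distance <- function(trajectory, config, cell_ids, axis = c(0, 1, 0)) {
  tr <- trajectory[trajectory$cell %in% cell_ids, , drop = FALSE]
  proj <- tr$x * axis[1] + tr$y * axis[2] + tr$z * axis[3]
  per_cell <- vapply(split(data.frame(mcs = tr$mcs, p = proj), tr$cell),
                     function(d) {
                       d <- d[order(d$mcs), ]
                       d$p[1] - d$p[nrow(d)]
                     }, numeric(1))
  mean(per_cell) * config$microns_per_voxel
}

#' Unpaired two-tailed Student's t-test
#'
#' Pooled-variance two-sample t statistic with p from the t distribution.
#' With zero pooled variance the p-value degenerates to 1 for equal means
#' and 0 otherwise.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @return list with `t`, `p`, `df`, and the two group means.
#' @export
t_test_independent <- function(sample_a, sample_b) {
  n1 <- length(sample_a); n2 <- length(sample_b)
  if (n1 < 2 || n2 < 2) stop("each sample needs n >= 2")
  m1 <- mean(sample_a); m2 <- mean(sample_b)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(sample_a) + (n2 - 1) * stats::var(sample_b)) / df
  if (sp2 == 0) {
    t <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    p <- if (m1 == m2) 1 else 0
  } else {
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * pt(-abs(t), df)
  }
  list(t = t, p = p, df = df, mean_a = m1, mean_b = m2)
}

#' One-way analysis of variance
#'
#' Standard between/within mean-square F with p from the F distribution.
#' Identical groups (zero between- and within-group variance) give
#' `F = 0, p = 1`.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `F`, `p`, and the degrees of freedom `df1`, `df2`.
#' @export
one_way_anova <- function(groups) {
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2)) stop("each group needs n >= 2")
  n <- vapply(groups, length, integer(1))
  N <- sum(n)
  gm <- vapply(groups, mean, numeric(1))
  grand <- sum(n * gm) / N
  ssb <- sum(n * (gm - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1; df2 <- N - k
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, p = 1, df1 = df1, df2 = df2))
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2))
  }
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = pf(F, df1, df2, lower.tail = FALSE), df1 = df1, df2 = df2)
}

#' Sensitivity as a regression slope
#'
#' Least-squares slope of the mean output versus the fractional parameter
#' change, the summary used to rank parameter sensitivities.
#'
#' @param levels fractional parameter changes (e.g. -0.5 ... 0.5).
#' @param mean_outputs mean output per level.
#' @return scalar slope.
#' @export
sensitivity_slope <- function(levels, mean_outputs) {
  if (length(levels) < 3) stop("need at least 3 levels")
  unname(coef(lm(mean_outputs ~ levels))[2])
}

#' Synthetic centroid trajectories
#'
#' Fixture generator for the metrics layer: straight-line drift along an
#' axis plus isotropic Gaussian jitter, independent of the simulation
#' engine. Uses R's RNG.
#'
#' @param n_cells number of tracked cells.
#' @param n_samples number of samples (>= 2).
#' @param drift displacement per sample along `axis`, voxels.
#' @param noise_sd Gaussian jitter s.d. per coordinate, voxels.
#' @param axis drift direction.
#' @param mcs_per_sample sampling interval, MCS.
#' @param origin starting centroid.
#' @return trajectory data.frame (sample, mcs, cell, x, y, z).
#' @export
synth_trajectory <- function(n_cells = 4, n_samples = 8, drift = 1,
                             noise_sd = 0, axis = c(0, 1, 0),
                             mcs_per_sample = 200, origin = c(20, 20, 4)) {
  out <- expand.grid(sample = seq_len(n_samples), cell = seq_len(n_cells))
  out$mcs <- (out$sample - 1) * mcs_per_sample
  base <- (out$sample - 1) * drift
  out$x <- origin[1] + base * axis[1] + stats::rnorm(nrow(out), 0, noise_sd)
  out$y <- origin[2] + base * axis[2] + stats::rnorm(nrow(out), 0, noise_sd)
  out$z <- origin[3] + base * axis[3] + stats::rnorm(nrow(out), 0, noise_sd)
  out$type <- "leader"
  out[, c("sample", "mcs", "cell", "type", "x", "y", "z")]
}

#' Synthetic gap-area time series
#'
#' Fixture generator for the closure metric: the gap side shrinks by `rate`
#' voxels per sample (floored at 0), with optional jitter on the side length.
#' Uses R's RNG.
#'
#' @param side0 initial side length, voxels.
#' @param rate side shrink per sample, voxels.
#' @param n_samples number of samples.
#' @param noise_sd Gaussian jitter s.d. on the side length.
#' @param mcs_per_sample sampling interval, MCS.
#' @return data.frame (sample, mcs, free_area).
#' @export
synth_area_record <- function(side0 = 40, rate = 2, n_samples = 8,
                              noise_sd = 0, mcs_per_sample = 200) {
  s <- seq_len(n_samples)
  side <- pmax(side0 - (s - 1) * rate + stats::rnorm(n_samples, 0, noise_sd), 0)
  data.frame(sample = s, mcs = (s - 1) * mcs_per_sample, free_area = side^2)
}
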
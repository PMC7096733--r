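# Shared fixtures. Simulated cohorts are expensive, so they are built once
# per test run and memoized in a session-level environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# small desk-scale config: 14 x 14 x 10 grid, 80 raw volumes
small_cfg <- function(..., seed = 1) {
  args <- utils::modifyList(
    list(grid_shape = c(14, 14, 10), n_timepoints = 80,
         effect_center = c(9, 6, 4), effect_radii = c(2.5, 2.5, 2.5),
         seed = seed),
    list(...))
  do.call(sim_config, args)
}

# tiny config for many-cohort calibration loops
tiny_cfg <- function(..., seed = 1) {
  args <- utils::modifyList(
    list(grid_shape = c(10, 10, 8), n_timepoints = 60,
         effect_center = c(7, 4, 4), effect_radii = c(1.5, 1.5, 1.5),
         seed = seed),
    list(...))
  do.call(sim_config, args)
}

# a single simulated session pair on the small grid (effect present in post)
small_session_pair <- function() fixture("small_session_pair", {
  cfg <- small_cfg(n_subjects = 2, seed = 3)
  truth <- ground_truth(cfg)
  post <- simulate_rest_session(cfg, "sub001", "High", "post", truth, 301)
  pre <- simulate_rest_session(cfg, "sub001", "High", "pre", truth, 302)
  list(cfg = cfg, truth = truth, post = post, pre = pre)
})

# null cohort (no injected effects) at the study's sample size; the small
# grid keeps it cheap. The full n matters: PAIR SVM held-out accuracy runs
# systematically below 0.5 on very small null cohorts (see test-pairsvm)
null_cohort <- function() fixture("null_cohort", {
  cfg <- small_cfg(n_subjects = 31, reho_effect = 0, dc_effect = 0,
                   seed = 11)
  panels <- compute_change_panels(cfg)
  c(panels, list(cfg = cfg))
})

# strong-amplitude effect cohort, 12 subjects on the small grid
strong_cohort <- function() fixture("strong_cohort", {
  cfg <- small_cfg(n_subjects = 12, reho_effect = 2.5, dc_effect = 2.5,
                   seed = 5)
  panels <- compute_change_panels(cfg)
  c(panels, list(cfg = cfg))
})

# recovery cohort at default amplitudes: 31 subjects, 18 x 18 x 14 grid
recovery_cohort <- function() fixture("recovery_cohort", {
  cfg <- sim_config(grid_shape = c(18, 18, 14), n_subjects = 31,
                    n_timepoints = 160, effect_center = c(12, 8, 6),
                    seed = 0)
  panels <- compute_change_panels(cfg)
  c(panels, list(cfg = cfg))
})

# three cohorts at increasing effect amplitude (fixed seed), 6 subjects;
# levels chosen below the saturation regime of the bounded metrics
amplitude_series <- function() fixture("amplitude_series", {
  lapply(c(0.25, 0.5, 1), function(amp) {
    cfg <- small_cfg(n_subjects = 6, reho_effect = amp, dc_effect = amp,
                     seed = 21)
    c(compute_change_panels(cfg), list(cfg = cfg, amp = amp))
  })
})

# coarse voxel lattice (spacing 3 voxels = 9 mm > noise FWHM): voxels far
# enough apart that their statistics are approximately independent
lattice_mask <- function(dims, spacing = 3) {
  out <- array(FALSE, dims)
  out[seq(2, dims[1], spacing), seq(2, dims[2], spacing),
      seq(2, dims[3], spacing)] <- TRUE
  out
}

# brute-force Kendall W via the mean pairwise Spearman correlation identity
# W = ((K - 1) * mean_rho + 1) / K  (valid without ties)
kcc_spearman_oracle <- function(series) {
  K <- ncol(series)
  pairs <- utils::combn(K, 2)
  rhos <- apply(pairs, 2, function(ij)
    stats::cor(series[, ij[1]], series[, ij[2]], method = "spearman"))
  ((K - 1) * mean(rhos) + 1) / K
}

# largest suprathreshold cluster and its overlap with the truth region
truth_overlap <- function(fmap, mask, effect_mask, voxel_p = 0.001) {
  p <- stat_p_values(fmap)
  supra <- (p < voxel_p) & mask
  if (!any(supra)) return(list(extent = 0L, overlap = 0))
  lab <- rehodc:::label_clusters(supra, 6)
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  list(extent = sizes[big],
       overlap = sum(lab[which(effect_mask)] == big) / sum(effect_mask))
}
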
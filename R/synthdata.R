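#' Simulation configuration for a synthetic resting-state cohort
#'
#' Defines the study conditions emulated by the generator: a within-subject
#' cohort scanned before and after each of three stimulation sessions (High,
#' Low, Sham), with an injectable local-synchronization (ReHo-like) effect and
#' hub-connectivity (DC-like) effect confined to an ellipsoidal ground-truth
#' region, present by default only in the post phase of the High condition.
#'
#' @param grid_shape voxel counts per axis (each >= 8).
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param tr_s repetition time in seconds.
#' @param n_timepoints raw volumes per resting run (an 8-minute run at
#'   TR = 2 s gives 240).
#' @param n_subjects cohort size.
#' @param noise_sd baseline noise standard deviation (signal units).
#' @param ar1_rho lag-1 temporal autocorrelation of the noise, in `[0, 1)`.
#' @param spatial_fwhm_mm spatial smoothness (FWHM) of the noise, mm.
#' @param effect_center ellipsoid center (voxel indices) of the ground-truth
#'   effect region, placed in the nominal right-cerebellum octant; default is
#'   the voxel at grid fractions (2/3, 3/8, 0.4), i.e. (16, 9, 7) on the
#'   default grid.
#' @param effect_radii ellipsoid radii in voxels (all > 0). The default is
#'   large relative to the 6-mm map-smoothing kernel: local-synchrony effects
#'   are genuinely suppressed in a one-voxel-deep boundary zone (mixed
#'   neighborhoods, mask-mean normalization), so recoverability requires the
#'   region interior to dominate its boundary shell.
#' @param reho_effect amplitude (signal units) of the shared neighborhood
#'   signal injected in the effect region.
#' @param dc_effect amplitude (signal units) of the extra global-signal
#'   coupling injected in the effect region.
#' @param global_amp baseline coupling of every in-mask voxel to the single
#'   global signal (signal units); gives the field a realistic nonzero
#'   connectivity floor so a hub effect can raise suprathreshold degree.
#' @param effect_condition,effect_phase the (condition, phase) cell carrying
#'   the injected effects.
#' @param between_subject_sd_frac SD of per-subject effect amplitudes as a
#'   fraction of the configured mean.
#' @param drift_sd SD across voxels of the total linear drift over a run.
#' @param motion_walk_sd_mm,motion_walk_sd_rad per-step SD of the motion
#'   random walk (translations mm, rotations radians).
#' @param motion_coupling_sd SD of per-voxel motion regression coefficients.
#' @param task_amp task activation amplitude (signal units).
#' @param task_n_timepoints volumes in the block-design task run (4 minutes at
#'   TR = 2 s gives 120).
#' @param task_target voxel indices of the simulated activation center;
#'   default is the voxel at grid fractions (1/3, 0.55, 0.75) in the nominal
#'   left motor cortex octant.
#' @param block_length_s task/rest block length in seconds.
#' @param seed base RNG seed for the cohort.
#' @return A `sim_config` list.
#' @export
sim_config <- function(grid_shape = c(24, 24, 18),
                       voxel_size_mm = 3,
                       tr_s = 2,
                       n_timepoints = 240,
                       n_subjects = 31,
                       noise_sd = 1,
                       ar1_rho = 0.3,
                       spatial_fwhm_mm = 6,
                       effect_center = NULL,
                       effect_radii = c(4, 4, 4),
                       reho_effect = 1,
                       dc_effect = 1,
                       global_amp = 0.45,
                       effect_condition = "High",
                       effect_phase = "post",
                       between_subject_sd_frac = 0.3,
                       drift_sd = 2,
                       motion_walk_sd_mm = 0.02,
                       motion_walk_sd_rad = 4e-4,
                       motion_coupling_sd = 0.1,
                       task_amp = 1.5,
                       task_n_timepoints = 120,
                       task_target = NULL,
                       block_length_s = 30,
                       seed = 0) {
  grid_shape <- as.integer(grid_shape)
  # default effect center sits in the right-posterior-inferior octant
  # (x = 2/3, y = 3/8, z = 0.4 of the grid); c(16, 9, 7) at the default grid
  if (is.null(effect_center))
    effect_center <- round(grid_shape * c(2 / 3, 3 / 8, 0.4))
  # default task target in the left-superior octant (the "hand knob" of the
  # phantom): c(8, 13, 14) at the default grid
  if (is.null(task_target))
    task_target <- round(grid_shape * c(1 / 3, 0.55, 0.75))
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = voxel_size_mm, tr_s = tr_s,
              n_timepoints = as.integer(n_timepoints),
              n_subjects = as.integer(n_subjects),
              noise_sd = noise_sd, ar1_rho = ar1_rho,
              spatial_fwhm_mm = spatial_fwhm_mm,
              effect_center = effect_center, effect_radii = effect_radii,
              reho_effect = reho_effect, dc_effect = dc_effect,
              global_amp = global_amp,
              effect_condition = effect_condition, effect_phase = effect_phase,
              between_subject_sd_frac = between_subject_sd_frac,
              drift_sd = drift_sd,
              motion_walk_sd_mm = motion_walk_sd_mm,
              motion_walk_sd_rad = motion_walk_sd_rad,
              motion_coupling_sd = motion_coupling_sd,
              task_amp = task_amp,
              task_n_timepoints = as.integer(task_n_timepoints),
              task_target = task_target,
              block_length_s = block_length_s,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 8L))
    stop("`grid_shape` must have 3 entries, each >= 8")
  if (cfg$ar1_rho < 0 || cfg$ar1_rho >= 1)
    stop("`ar1_rho` must lie in [0, 1)")
  if (cfg$n_timepoints <= 10L)
    stop("`n_timepoints` must exceed 10")
  if (cfg$tr_s <= 0) stop("`tr_s` must be > 0")
  if (cfg$n_subjects < 1L) stop("`n_subjects` must be >= 1")
  if (any(cfg$effect_radii <= 0))
    stop("configuration error: effect region radii must be > 0 (empty region)")
  invisible(cfg)
}

conditions <- function() c("High", "Low", "Sham")
phases <- function() c("pre", "post")

# ellipsoidal effect region from the config (logical 3D array)
effect_region_mask <- function(cfg) {
  d <- cfg$grid_shape
  idx <- index_to_ijk(seq_len(prod(d)), d)
  z <- sweep(sweep(idx, 2L, cfg$effect_center, `-`), 2L, cfg$effect_radii, `/`)
  array(rowSums(z^2) <= 1, dim = d)
}

#' Generate the synthetic gray-matter mask
#'
#' A smooth tissue-probability blob (an ellipsoidal falloff plus seeded smooth
#' noise) thresholded at probability 0.2; the largest face-connected component
#' is kept. The mask covers roughly 30-60% of the grid. The configured effect
#' region must lie at least 90% inside the thresholded blob (else a
#' configuration error); the remaining boundary sliver is absorbed into the
#' mask, since the ground-truth region is tissue by construction.
#'
#' @param cfg a [sim_config()].
#' @return Logical 3D array.
#' @export
make_mask <- function(cfg) {
  validate_sim_config(cfg)
  local_seed(cfg$seed)
  d <- cfg$grid_shape
  center <- (d + 1) / 2
  radii <- 0.37 * d
  idx <- index_to_ijk(seq_len(prod(d)), d)
  z <- sweep(sweep(idx, 2L, center, `-`), 2L, radii, `/`)
  prob <- array(exp(-rowSums(z^2)), dim = d)
  sigma_vox <- fwhm_to_sigma(cfg$spatial_fwhm_mm) / cfg$voxel_size_mm
  bump <- smooth3d(array(stats::rnorm(prod(d)), dim = d), rep(sigma_vox, 3))
  prob <- prob + 0.05 * bump / stats::sd(bump)
  mask <- largest_component(prob > 0.2, connectivity = 6)
  eff <- effect_region_mask(cfg)
  if (sum(eff) == 0L)
    stop("configuration error: effect region is empty")
  coverage <- mean(mask[eff])
  if (coverage < 0.9)
    stop("configuration error: effect region extends outside the mask (",
         round(100 * (1 - coverage)), "% outside)")
  # absorb boundary wiggle: the ground-truth region is tissue by construction
  mask | eff
}

#' Ground truth of a simulated cohort
#'
#' Records what was injected where: the effect region, the (condition, phase)
#' cell carrying it, the mean amplitudes, and the per-subject amplitudes drawn
#' around those means.
#'
#' @param cfg a [sim_config()].
#' @return A `ground_truth` list with elements `mask` (gray matter),
#'   `effect_mask`, `condition`, `phase`, `reho_effect`, `dc_effect`,
#'   `subject_amp` (data frame of per-subject amplitudes) and `seed`.
#' @export
ground_truth <- function(cfg) {
  mask <- make_mask(cfg)
  eff <- effect_region_mask(cfg)
  local_seed(cfg$seed + 1L)
  n <- cfg$n_subjects
  draw <- function(mu) {
    if (mu == 0) rep(0, n)
    else pmax(0, stats::rnorm(n, mu, cfg$between_subject_sd_frac * mu))
  }
  amp <- data.frame(subject_id = subject_ids(n),
                    reho_amp = draw(cfg$reho_effect),
                    dc_amp = draw(cfg$dc_effect))
  structure(list(mask = mask, effect_mask = eff,
                 condition = cfg$effect_condition, phase = cfg$effect_phase,
                 reho_effect = cfg$reho_effect, dc_effect = cfg$dc_effect,
                 subject_amp = amp, seed = cfg$seed),
            class = "ground_truth")
}

subject_ids <- function(n) sprintf("sub%03d", seq_len(n))

# deterministic per-session seed, kept well below 2^31
session_seed <- function(base, subject_idx, condition, phase) {
  ci <- match(condition, conditions())
  pi_ <- match(phase, c(phases(), "task"))
  (base %% 100000L) + 6000L * subject_idx + 7L * ci + 2L * pi_
}

# band-limited unit-variance signals: white noise restricted to [low, high] Hz
band_limited_series <- function(n_t, tr_s, n_series = 1L,
                                low_hz = 0.01, high_hz = 0.08) {
  x <- matrix(stats::rnorm(n_t * n_series), n_t, n_series)
  y <- fft_bandpass(x, tr_s, low_hz, high_hz)
  sweep(y, 2L, apply(y, 2L, stats::sd), `/`)
}

# spatially smooth AR(1) noise field, per-voxel temporal SD rescaled to sd
noise_field <- function(d, n_t, sigma_vox, rho, sd) {
  w <- array(stats::rnorm(prod(d) * n_t), dim = c(d, n_t))
  if (any(sigma_vox > 0)) w <- smooth4d_spatial(w, sigma_vox)
  m <- t(matrix(w, prod(d), n_t))           # t x V
  if (rho > 0)
    m <- apply(m, 2L, function(col) as.numeric(stats::filter(col, rho,
                                                 method = "recursive")))
  s <- sqrt(colMeans(m^2) - colMeans(m)^2)
  s[s == 0] <- 1
  sweep(m, 2L, s, `/`) * sd
}

#' Simulate one resting-state session
#'
#' Per voxel v the signal model is
#' `y_v(t) = 100 + a_s g_v(t) I(effect) + b_s h(t) I(effect) + c h(t) I(mask)
#'  + drift_v t + M(t) gamma_v + eps_v(t)`,
#' where `eps` is AR(1), spatially smoothed noise; `g` is a band-limited
#' (0.01-0.08 Hz) field shared across neighboring voxels inside the effect
#' region, extended one voxel beyond it so every region voxel has a fully
#' synchronized neighborhood (raises local synchrony, hence ReHo); `h` is one band-limited global
#' signal carried weakly (`c = global_amp`) by all in-mask voxels and strongly
#' (extra `b_s`) by effect voxels in the effect cell (raises whole-brain
#' degree, hence DC); `M` are six simulated motion parameters. Amplitudes
#' `a_s`, `b_s` are the subject's draws in `truth` and are nonzero only in the
#' (condition, phase) cell named there.
#'
#' @param cfg a [sim_config()].
#' @param subject subject id (must appear in `truth$subject_amp`).
#' @param condition one of High, Low, Sham.
#' @param phase `"pre"` or `"post"`.
#' @param truth a [ground_truth()] consistent with `cfg`.
#' @param seed RNG seed for this session.
#' @return A list with `bold` (a [bold4d()]) and `motion` (data frame of six
#'   motion parameters: three translations in mm, three rotations in radians).
#' @export
simulate_rest_session <- function(cfg, subject, condition, phase, truth,
                                  seed) {
  validate_sim_config(cfg)
  condition <- match.arg(condition, conditions())
  phase <- match.arg(phase, phases())
  local_seed(seed)
  d <- cfg$grid_shape
  n_t <- cfg$n_timepoints
  V <- prod(d)
  sigma_vox <- rep(fwhm_to_sigma(cfg$spatial_fwhm_mm) / cfg$voxel_size_mm, 3)

  y <- noise_field(d, n_t, sigma_vox, cfg$ar1_rho, cfg$noise_sd)   # t x V

  mask_v <- as.vector(truth$mask)
  eff_v <- as.vector(truth$effect_mask)
  row <- match(subject, truth$subject_amp$subject_id)
  if (is.na(row)) stop("unknown subject id: ", subject)
  effect_on <- identical(condition, truth$condition) &&
    identical(phase, truth$phase)
  a <- if (effect_on) truth$subject_amp$reho_amp[row] else 0
  b <- if (effect_on) truth$subject_amp$dc_amp[row] else 0

  # single global signal: weak everywhere in mask, extra coupling in effect
  h <- band_limited_series(n_t, cfg$tr_s, 1L)[, 1]
  y[, mask_v] <- y[, mask_v] + cfg$global_amp *
    tcrossprod(h, rep(1, sum(mask_v)))
  if (b != 0)
    y[, eff_v] <- y[, eff_v] + b * tcrossprod(h, rep(1, sum(eff_v)))

  # neighborhood-shared band-limited field over the effect region; the field
  # extends one voxel beyond the region (within the mask) so that every
  # region voxel has a fully synchronized neighborhood
  if (a != 0) {
    eff_dil <- as.vector(dilate_mask(truth$effect_mask, 6)) & mask_v
    bb <- apply(index_to_ijk(which(eff_dil), d), 2L, range)
    lo <- pmax(bb[1, ] - 2L, 1L); hi <- pmin(bb[2, ] + 2L, d)
    db <- hi - lo + 1L
    g <- array(t(band_limited_series(n_t, cfg$tr_s, prod(db))),
               dim = c(db, n_t))
    # coherence scale of 2 voxels: neighbors share ~94% of the field, well
    # above the smoothed-noise + global-signal baseline, so the injection
    # raises (rather than dilutes) neighborhood concordance
    g <- smooth4d_spatial(g, rep(2, 3))
    gm <- t(matrix(g, prod(db), n_t))
    gm <- sweep(gm, 2L, apply(gm, 2L, stats::sd), `/`)
    sub_idx <- which(array(eff_dil, dim = d)[lo[1]:hi[1], lo[2]:hi[2],
                                             lo[3]:hi[3]])
    full_idx <- which(eff_dil)
    y[, full_idx] <- y[, full_idx] + a * gm[, sub_idx]
  }

  # linear drift, baseline 100
  tvec <- (seq_len(n_t) - 1) * cfg$tr_s
  duration <- max(tvec)
  slope <- stats::rnorm(V, 0, cfg$drift_sd / duration)
  y <- y + outer(tvec, slope) + 100

  # motion random walk and its coupling into the data
  steps <- cbind(matrix(stats::rnorm(n_t * 3, 0, cfg$motion_walk_sd_mm), n_t),
                 matrix(stats::rnorm(n_t * 3, 0, cfg$motion_walk_sd_rad), n_t))
  M <- apply(steps, 2L, cumsum)
  gamma <- matrix(stats::rnorm(6 * V, 0, cfg$motion_coupling_sd), 6, V)
  y <- y + scale(M, center = TRUE, scale = FALSE) %*% gamma

  motion <- as.data.frame(M)
  names(motion) <- motion_columns()
  list(bold = bold4d(array(t(y), dim = c(d, n_t)), cfg$tr_s,
                     cfg$voxel_size_mm),
       motion = motion)
}

motion_columns <- function() {
  c("trans_x_mm", "trans_y_mm", "trans_z_mm",
    "rot_x_rad", "rot_y_rad", "rot_z_rad")
}

#' Simulate one block-design task session
#'
#' Alternating rest/task blocks (rest first) of `block_length_s` seconds; the
#' task signal is the boxcar convolved with the canonical HRF, carried by a
#' Gaussian spatial bump centered on `target_center`. Elsewhere the run is
#' noise only (plus baseline and drift).
#'
#' @param cfg a [sim_config()].
#' @param subject subject id (recorded in provenance only).
#' @param target_center voxel indices of the activation center; must lie
#'   inside the gray-matter mask.
#' @param seed RNG seed.
#' @param amplitude activation amplitude in signal units; defaults to
#'   `cfg$task_amp`.
#' @return A [bold4d()] with `cfg$task_n_timepoints` volumes.
#' @export
simulate_task_session <- function(cfg, subject, target_center, seed,
                                  amplitude = cfg$task_amp) {
  validate_sim_config(cfg)
  mask <- make_mask(cfg)
  tc <- as.integer(round(target_center))
  if (any(tc < 1L) || any(tc > cfg$grid_shape) ||
      !mask[tc[1], tc[2], tc[3]])
    stop("`target_center` lies outside the gray-matter mask")
  local_seed(seed)
  d <- cfg$grid_shape
  n_t <- cfg$task_n_timepoints
  sigma_vox <- rep(fwhm_to_sigma(cfg$spatial_fwhm_mm) / cfg$voxel_size_mm, 3)
  y <- noise_field(d, n_t, sigma_vox, cfg$ar1_rho, cfg$noise_sd)

  bd <- block_design(tr_s = cfg$tr_s, n_timepoints = n_t,
                     block_length_s = cfg$block_length_s)
  reg <- task_regressor(bd)
  idx <- index_to_ijk(seq_len(prod(d)), d)
  dist2 <- rowSums(sweep(idx, 2L, tc, `-`)^2)
  profile <- exp(-dist2 / (2 * 1.5^2))
  profile[as.vector(!mask)] <- 0
  y <- y + amplitude * outer(reg, profile)

  tvec <- (seq_len(n_t) - 1) * cfg$tr_s
  slope <- stats::rnorm(prod(d), 0, cfg$drift_sd / max(tvec))
  y <- y + outer(tvec, slope) + 100
  bold4d(array(t(y), dim = c(d, n_t)), cfg$tr_s, cfg$voxel_size_mm)
}

#' Plan a synthetic cohort without generating data
#'
#' Returns the ground truth plus per-session seeds and identifiers, so
#' sessions can be generated on demand (one at a time) or written to disk by
#' [simulate_cohort()].
#'
#' @param cfg a [sim_config()].
#' @return List with `truth`, `rest` (data frame subject_id, condition, phase,
#'   seed) and `task` (data frame subject_id, seed).
#' @export
cohort_plan <- function(cfg) {
  truth <- ground_truth(cfg)
  ids <- subject_ids(cfg$n_subjects)
  rest <- expand.grid(phase = phases(), condition = conditions(),
                      subject_id = ids, stringsAsFactors = FALSE)
  rest <- rest[, c("subject_id", "condition", "phase")]
  rest$seed <- mapply(function(s, cnd, ph)
    session_seed(cfg$seed, match(s, ids), cnd, ph),
    rest$subject_id, rest$condition, rest$phase)
  task <- data.frame(subject_id = ids,
                     seed = vapply(seq_along(ids), function(i)
                       session_seed(cfg$seed, i, "High", "task"), numeric(1)))
  list(truth = truth, rest = rest, task = task)
}

#' Simulate a full cohort to disk
#'
#' Writes one NIfTI + motion TSV per resting session, one NIfTI per task
#' session, the gray-matter and effect masks, and a session manifest TSV.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return List with `manifest` (data frame: subject_id, condition, phase,
#'   bold_path, motion_path), `task_manifest`, `truth`, and `paths`.
#' @export
simulate_cohort <- function(cfg, dir) {
  plan <- cohort_plan(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- plan$rest
  man$bold_path <- file.path(dir, sprintf("%s_%s_%s_bold.nii",
                                          man$subject_id, man$condition,
                                          man$phase))
  man$motion_path <- file.path(dir, sprintf("%s_%s_%s_motion.tsv",
                                            man$subject_id, man$condition,
                                            man$phase))
  for (i in seq_len(nrow(man))) {
    ses <- simulate_rest_session(cfg, man$subject_id[i], man$condition[i],
                                 man$phase[i], plan$truth, man$seed[i])
    write_bold(ses$bold, man$bold_path[i])
    utils::write.table(ses$motion, man$motion_path[i], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tman <- plan$task
  tman$bold_path <- file.path(dir, sprintf("%s_task_bold.nii",
                                           tman$subject_id))
  for (i in seq_len(nrow(tman))) {
    bold <- simulate_task_session(cfg, tman$subject_id[i], cfg$task_target,
                                  tman$seed[i])
    write_bold(bold, tman$bold_path[i])
  }
  mask_path <- file.path(dir, "gm_mask.nii")
  eff_path <- file.path(dir, "effect_mask.nii")
  write_mask(plan$truth$mask, mask_path, cfg$voxel_size_mm)
  write_mask(plan$truth$effect_mask, eff_path, cfg$voxel_size_mm)
  manifest_path <- file.path(dir, "manifest.tsv")
  write_manifest(man[, c("subject_id", "condition", "phase",
                         "bold_path", "motion_path")], manifest_path)
  list(manifest = man, task_manifest = tman, truth = plan$truth,
       paths = list(mask = mask_path, effect_mask = eff_path,
                    manifest = manifest_path))
}

#' Read / write a session manifest TSV
#'
#' Columns: subject_id, condition, phase, bold_path, motion_path.
#'
#' @param manifest data frame to write.
#' @param path TSV path.
#' @return `read_manifest` returns the data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
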
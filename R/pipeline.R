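# Stage orchestration used by the analysis drivers, the tests and the
# acceptance script: session -> cleaned series -> normalized, smoothed metric
# maps -> per-contrast change panels.

#' Metric maps for one cleaned session
#'
#' Runs the fixed metric order on one session: cleaning
#' (discard, Friston-24 + trend regression, band-pass), ReHo and DC on the
#' unsmoothed filtered series, mask-mean normalization, then Gaussian
#' smoothing of the normalized maps.
#'
#' @param bold raw [bold4d()].
#' @param motion 6-column motion table for the raw run.
#' @param mask logical 3D gray-matter mask.
#' @param metric_cfg a [metric_config()].
#' @param discard initial volumes to drop.
#' @param low_hz,high_hz band-pass edges.
#' @param smooth_fwhm_mm smoothing applied to the normalized maps (mm).
#' @return List with smoothed `mReHo` and `mDC` [metric_map()]s.
#' @export
compute_session_maps <- function(bold, motion, mask,
                                 metric_cfg = metric_config(),
                                 discard = 10, low_hz = 0.01, high_hz = 0.08,
                                 smooth_fwhm_mm = 6) {
  clean <- preprocess_rest(bold, motion, discard, low_hz, high_hz)
  mreho <- smooth_map(normalize_by_mask_mean(reho_map(clean, mask,
                                                      metric_cfg)),
                      smooth_fwhm_mm)
  mdc <- smooth_map(normalize_by_mask_mean(dc_map(clean, mask, metric_cfg)),
                    smooth_fwhm_mm)
  list(mReHo = mreho, mDC = mdc)
}

#' Post-minus-pre change panels for a simulated cohort
#'
#' Generates every resting session of the cohort in memory (one at a time),
#' computes the smoothed normalized metric maps, and assembles per-metric
#' change panels (subjects x conditions x voxels).
#'
#' @param cfg a [sim_config()].
#' @param metric_cfg a [metric_config()].
#' @param discard,low_hz,high_hz,smooth_fwhm_mm pipeline parameters.
#' @param plan optional precomputed [cohort_plan()] (to reuse its ground
#'   truth).
#' @return List: `ReHo` and `DC` [change_panel()]s, plus `truth`.
#' @export
compute_change_panels <- function(cfg, metric_cfg = metric_config(),
                                  discard = 10, low_hz = 0.01,
                                  high_hz = 0.08, smooth_fwhm_mm = 6,
                                  plan = NULL) {
  if (is.null(plan)) plan <- cohort_plan(cfg)
  truth <- plan$truth
  ids <- unique(plan$rest$subject_id)
  reho_maps <- dc_maps <- stats::setNames(vector("list", length(ids)), ids)
  for (s in ids) {
    reho_maps[[s]] <- dc_maps[[s]] <- list()
    for (cond in conditions()) {
      per_phase <- list()
      for (ph in phases()) {
        row <- plan$rest[plan$rest$subject_id == s &
                           plan$rest$condition == cond &
                           plan$rest$phase == ph, ]
        ses <- simulate_rest_session(cfg, s, cond, ph, truth, row$seed)
        per_phase[[ph]] <- compute_session_maps(ses$bold, ses$motion,
                                                truth$mask, metric_cfg,
                                                discard, low_hz, high_hz,
                                                smooth_fwhm_mm)
      }
      reho_maps[[s]][[cond]] <- change_map(per_phase$post$mReHo,
                                           per_phase$pre$mReHo)
      dc_maps[[s]][[cond]] <- change_map(per_phase$post$mDC,
                                         per_phase$pre$mDC)
    }
  }
  list(ReHo = change_panel(reho_maps), DC = change_panel(dc_maps),
       truth = truth)
}

#' Change panels from an on-disk cohort manifest
#'
#' File-based variant of [compute_change_panels()]: reads each session's
#' NIfTI volume and motion TSV from the manifest written by
#' [simulate_cohort()].
#'
#' @param manifest data frame with subject_id, condition, phase, bold_path,
#'   motion_path.
#' @param mask logical 3D gray-matter mask.
#' @inheritParams compute_change_panels
#' @return List with `ReHo` and `DC` [change_panel()]s.
#' @export
panels_from_manifest <- function(manifest, mask,
                                 metric_cfg = metric_config(),
                                 discard = 10, low_hz = 0.01,
                                 high_hz = 0.08, smooth_fwhm_mm = 6) {
  ids <- unique(manifest$subject_id)
  reho_maps <- dc_maps <- stats::setNames(vector("list", length(ids)), ids)
  for (s in ids) {
    reho_maps[[s]] <- dc_maps[[s]] <- list()
    for (cond in unique(manifest$condition)) {
      per_phase <- list()
      for (ph in phases()) {
        row <- manifest[manifest$subject_id == s &
                          manifest$condition == cond &
                          manifest$phase == ph, ]
        if (nrow(row) != 1)
          stop("manifest must have exactly one (subject, condition, phase) ",
               "row; got ", nrow(row), " for ", s, "/", cond, "/", ph)
        bold <- read_bold(row$bold_path)
        motion <- utils::read.table(row$motion_path, header = TRUE,
                                    sep = "\t")
        per_phase[[ph]] <- compute_session_maps(bold, motion, mask,
                                                metric_cfg, discard, low_hz,
                                                high_hz, smooth_fwhm_mm)
      }
      reho_maps[[s]][[cond]] <- change_map(per_phase$post$mReHo,
                                           per_phase$pre$mReHo)
      dc_maps[[s]][[cond]] <- change_map(per_phase$post$mDC,
                                         per_phase$pre$mDC)
    }
  }
  list(ReHo = change_panel(reho_maps), DC = change_panel(dc_maps))
}

#' Residual change maps for smoothness estimation
#'
#' Per-voxel residuals of the panel after removing subject and condition
#' means (the repeated-measures error term), returned as one 3D array per
#' subject-condition cell. These are the residual fields whose smoothness
#' calibrates the Gaussian-field cluster correction.
#'
#' @param panel a [change_panel()].
#' @return List of 3D arrays (length n x k).
#' @export
panel_residual_maps <- function(panel) {
  stopifnot(inherits(panel, "change_panel"))
  n <- dim(panel$data)[1]; k <- dim(panel$data)[2]
  cond_means <- apply(panel$data, c(2, 3), mean)
  subj_means <- apply(panel$data, c(1, 3), mean)
  grand <- colMeans(cond_means)
  out <- vector("list", n * k)
  idx <- 1L
  for (i in seq_len(n)) for (j in seq_len(k)) {
    r <- panel$data[i, j, ] - subj_means[i, ] - cond_means[j, ] + grand
    r[!as.vector(panel$mask)] <- 0
    out[[idx]] <- array(r, panel$dims)
    idx <- idx + 1L
  }
  out
}
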
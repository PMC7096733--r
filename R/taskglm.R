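# Subject-level block-design GLM and peak localization: canonical HRF,
# boxcar design with discrete-cosine high-pass set, voxelwise OLS t map, and
# peak search for individualized stimulation-target selection.

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peak at 6 s, undershoot peak at
#' 16 s, undershoot ratio 1/6), sampled at the TR and peak-normalized to 1.
#'
#' @param tr_s sampling interval in seconds (> 0).
#' @param duration_s kernel length in seconds.
#' @return Numeric vector sampled at `0, tr_s, 2 tr_s, ...`.
#' @export
canonical_hrf <- function(tr_s, duration_s = 32) {
  if (tr_s <= 0) stop("`tr_s` must be > 0")
  t <- seq(0, duration_s, by = tr_s)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Block-design description
#'
#' Alternating rest/task blocks starting with rest; block boundaries must
#' align to the TR and the total duration is `n_timepoints * tr_s`.
#'
#' @param tr_s repetition time (s).
#' @param n_timepoints number of volumes.
#' @param block_length_s block length in seconds (default 30).
#' @param high_pass_cutoff_s high-pass cutoff period in seconds (default 128).
#' @return A `block_design` list.
#' @export
block_design <- function(tr_s = 2, n_timepoints = 120, block_length_s = 30,
                         high_pass_cutoff_s = 128) {
  if (block_length_s %% tr_s != 0)
    stop("block boundaries must align to the TR")
  structure(list(tr_s = tr_s, n_timepoints = as.integer(n_timepoints),
                 block_length_s = block_length_s,
                 high_pass_cutoff_s = high_pass_cutoff_s),
            class = "block_design")
}

# boxcar (0 rest / 1 task, rest first) convolved with the canonical HRF,
# sampled at volume onsets
task_regressor <- function(bd) {
  onsets <- (seq_len(bd$n_timepoints) - 1) * bd$tr_s
  boxcar <- as.numeric((onsets %/% bd$block_length_s) %% 2 == 1)
  h <- canonical_hrf(bd$tr_s)
  conv <- stats::convolve(boxcar, rev(h), type = "open")[seq_len(bd$n_timepoints)]
  conv
}

#' Build the GLM design matrix for a block design
#'
#' Columns: intercept, mean-centered task regressor (boxcar convolved with the
#' canonical HRF), and a discrete-cosine high-pass set spanning periods longer
#' than the cutoff (`floor(2 * total_duration / cutoff)` columns).
#'
#' @param bd a [block_design()].
#' @return List with `X` (t x p matrix), `task_col` (index of the task
#'   column).
#' @export
build_design <- function(bd) {
  stopifnot(inherits(bd, "block_design"))
  n <- bd$n_timepoints
  task <- task_regressor(bd)
  if (all(task == 0)) stop("degenerate design: task regressor is all zero")
  task <- task - mean(task)
  total_s <- n * bd$tr_s
  n_cos <- floor(2 * total_s / bd$high_pass_cutoff_s)
  tt <- seq_len(n) - 1
  dct <- if (n_cos >= 1)
    vapply(seq_len(n_cos), function(k)
      cos(pi * (2 * tt + 1) * k / (2 * n)), numeric(n))
  else NULL
  X <- cbind(intercept = 1, task = task, dct)
  if (!is.null(dct))
    colnames(X)[-(1:2)] <- paste0("cos", seq_len(n_cos))
  list(X = X, task_col = 2L)
}

#' Voxelwise GLM t map for the task regressor
#'
#' Per voxel OLS fit of the design; `t = beta_task / SE(beta_task)` with
#' `df = n - rank(X)`. Zero-residual voxels yield `t = Inf` with the sign of
#' the estimate (0 when the estimate is also 0), never `NaN`.
#'
#' @param bold a [bold4d()].
#' @param design output of [build_design()] (or a compatible list).
#' @param mask optional logical 3D mask restricting the fit.
#' @return A [stat_map()] of t values.
#' @export
glm_t_map <- function(bold, design, mask = NULL) {
  stopifnot(inherits(bold, "bold4d"))
  X <- design$X
  n <- n_timepoints(bold)
  if (nrow(X) != n) stop("design rows do not match volumes")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("rank-deficient design matrix")
  d <- grid_dim(bold)
  if (is.null(mask)) mask <- array(TRUE, d)
  Y <- bold_matrix(bold)[, as.vector(mask), drop = FALSE]
  beta <- qr.coef(qrx, Y)
  res <- qr.resid(qrx, Y)
  df <- n - qrx$rank
  sigma2 <- colSums(res^2) / df
  xtx_inv <- solve(crossprod(X))
  se <- sqrt(sigma2 * xtx_inv[design$task_col, design$task_col])
  b <- beta[design$task_col, ]
  # numerically zero residuals (perfect fit) give a signed infinite t
  degenerate <- se <= sqrt(.Machine$double.eps) * abs(b)
  tval <- ifelse(degenerate, sign(b) * Inf, b / se)
  tval[degenerate & b == 0] <- 0
  out <- array(0, d)
  out[mask] <- tval
  stat_map(out, df = df, mask = mask, stat = "t",
           voxel_size_mm = bold$voxel_size_mm)
}

#' Locate the peak statistic inside a search mask
#'
#' Returns the maximum-t voxel within `search_mask`; ties are broken by the
#' lowest linear index. If no voxel has t > 0 a warning is issued and the
#' maximum is still returned.
#'
#' @param tmap a [stat_map()].
#' @param search_mask logical 3D array (nonempty).
#' @return A list: `voxel` (1-based indices), `world_mm`, `t`, `p`
#'   (two-tailed; the positive tail drives peak selection).
#' @export
locate_target <- function(tmap, search_mask) {
  stopifnot(inherits(tmap, "stat_map"))
  if (sum(search_mask) == 0L) stop("empty search mask")
  v <- tmap$values
  v[!search_mask] <- -Inf
  peak_lin <- which.max(v)
  peak_t <- tmap$values[peak_lin]
  if (peak_t <= 0)
    warning("no voxel with t > 0 inside the search mask")
  ijk <- index_to_ijk(peak_lin, dim(v))[1, ]
  p <- if (is.infinite(peak_t)) 0
  else 2 * stats::pt(abs(peak_t), tmap$df[1], lower.tail = FALSE)
  list(voxel = ijk,
       world_mm = voxel_to_world(ijk, tmap$voxel_size_mm),
       t = peak_t, p = p)
}
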
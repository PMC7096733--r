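# Voxel-level resting-state metrics: regional homogeneity (Kendall's W over a
# voxel's neighborhood) and weighted positive degree centrality, plus their
# mask-mean normalizations and post-minus-pre change maps.

#' Kendall's coefficient of concordance
#'
#' W over K rankers (time series) and n items (time points): each series is
#' ranked over time (average ranks for ties), the rank sums
#' `R_t = sum_k rank_k(t)` are formed, and
#' `W = sum_t (R_t - R.bar)^2 / ((1/12) K^2 (n^3 - n))` with
#' `R.bar = K (n + 1) / 2`. No tie-correction term is applied (ties are
#' measure-zero in float data); a note is emitted when any series is constant,
#' since all-tied ranks deflate W.
#'
#' @param series numeric n x K matrix: K time series of length n as columns.
#' @return W in `[0, 1]` (up to floating-point epsilon).
#' @export
kcc <- function(series) {
  m <- as.matrix(series)
  n <- nrow(m); K <- ncol(m)
  if (K < 2 || n < 2) stop("need K >= 2 series of length n >= 2")
  if (any(apply(m, 2L, function(col) all(col == col[1]))))
    message("kcc: constant series present; average ranks used (W deflated)")
  rk <- apply(m, 2L, rank)          # ties.method = "average"
  r_t <- rowSums(rk)
  sum((r_t - K * (n + 1) / 2)^2) / (K^2 * (n^3 - n) / 12)
}

#' Metric computation parameters
#'
#' @param reho_neighborhood 7 (center + 6 face neighbors), 19 (+12 edge) or
#'   27 (+8 corner).
#' @param dc_r_threshold correlation cutoff in (-1, 1); connections with
#'   `r > threshold` (strict) count.
#' @param dc_weighted sum correlation values (TRUE) rather than counts.
#' @param dc_positive_only exclude negative connections.
#' @return A `metric_config` list.
#' @export
metric_config <- function(reho_neighborhood = 7, dc_r_threshold = 0.25,
                          dc_weighted = TRUE, dc_positive_only = TRUE) {
  if (!reho_neighborhood %in% c(7, 19, 27))
    stop("`reho_neighborhood` must be 7, 19 or 27")
  if (dc_r_threshold <= -1 || dc_r_threshold >= 1)
    stop("`dc_r_threshold` must lie in (-1, 1)")
  structure(list(reho_neighborhood = as.integer(reho_neighborhood),
                 dc_r_threshold = dc_r_threshold,
                 dc_weighted = isTRUE(dc_weighted),
                 dc_positive_only = isTRUE(dc_positive_only)),
            class = "metric_config")
}

#' Regional homogeneity map
#'
#' Per in-mask voxel, Kendall's W ([kcc()]) of the voxel's time series with
#' its in-mask neighbors (neighborhood of 7, 19 or 27 including the center).
#' Voxels with fewer than 2 in-mask neighborhood members get 0.
#'
#' @param bold a preprocessed [bold4d()].
#' @param mask logical 3D gray-matter mask.
#' @param cfg a [metric_config()].
#' @return A [metric_map()] of kind `"ReHo"`.
#' @export
reho_map <- function(bold, mask, cfg = metric_config()) {
  stopifnot(inherits(bold, "bold4d"))
  if (sum(mask) == 0L) stop("empty mask")
  d <- grid_dim(bold)
  n <- n_timepoints(bold)
  Y <- bold_matrix(bold)
  rk <- matrix(0, n, ncol(Y))
  in_mask <- which(as.vector(mask))
  rk[, in_mask] <- apply(Y[, in_mask, drop = FALSE], 2L, rank)
  offs <- neighborhood_offsets(cfg$reho_neighborhood)
  maskn <- array(as.numeric(mask), d)
  S <- array(0, c(d, n))      # rank sums per voxel over neighborhood
  Kc <- array(0, d)           # in-mask neighborhood size per voxel
  rk4 <- array(t(rk), dim = c(d, n))
  for (o in seq_len(nrow(offs))) {
    off <- offs[o, ]
    Kc <- Kc + shift3d(maskn, off)
    if (all(off == 0)) S <- S + rk4
    else {
      sh <- array(0, c(d, n))
      for (t_i in seq_len(n)) sh[, , , t_i] <- shift3d(rk4[, , , t_i], off)
      S <- S + sh
    }
  }
  Sm <- matrix(S, prod(d), n)
  Kv <- as.vector(Kc)
  ss <- rowSums((Sm - Kv * (n + 1) / 2)^2)
  W <- ss / (Kv^2 * (n^3 - n) / 12)
  W[Kv < 2 | !as.vector(mask)] <- 0
  W <- pmin(pmax(W, 0), 1)
  metric_map(array(W, d), "ReHo", mask, bold$voxel_size_mm,
             provenance = list(neighborhood = cfg$reho_neighborhood))
}

#' Weighted positive degree-centrality map
#'
#' For every in-mask voxel i, `DC(i) = sum_{j != i} r_ij * 1[r_ij > thr]`
#' (Pearson correlation over time, self excluded, restricted to the mask).
#' With `dc_weighted = FALSE` connections are counted instead of summed.
#' Zero-variance voxels get all correlations set to 0 (flagged via a message).
#'
#' @param bold a preprocessed [bold4d()].
#' @param mask logical 3D gray-matter mask (>= 2 voxels).
#' @param cfg a [metric_config()].
#' @param block column block size for the correlation computation (memory
#'   control only; the result is identical).
#' @return A [metric_map()] of kind `"DC"`.
#' @export
dc_map <- function(bold, mask, cfg = metric_config(), block = 2000L) {
  stopifnot(inherits(bold, "bold4d"))
  if (sum(mask) < 2L) stop("need at least 2 in-mask voxels")
  d <- grid_dim(bold)
  n <- n_timepoints(bold)
  Y <- bold_matrix(bold)[, as.vector(mask), drop = FALSE]
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2L, mu)
  s <- sqrt(colSums(Yc^2))
  zero_var <- s == 0
  if (any(zero_var)) {
    message("dc_map: ", sum(zero_var),
            " zero-variance voxel(s); correlations set to 0")
    s[zero_var] <- 1
  }
  Z <- sweep(Yc, 2L, s, `/`)
  Z[, zero_var] <- 0
  V <- ncol(Z)
  thr <- cfg$dc_r_threshold
  dc <- numeric(V)
  for (start in seq(1L, V, by = block)) {
    idx <- start:min(start + block - 1L, V)
    R <- crossprod(Z, Z[, idx, drop = FALSE])      # V x |idx| correlations
    keep <- R > thr
    contrib <- if (cfg$dc_weighted) R * keep else keep * 1
    dc[idx] <- colSums(contrib)
    # remove the self term r_ii = 1 (absent for zero-variance voxels)
    self_r <- ifelse(zero_var[idx], 0, 1)
    dc[idx] <- dc[idx] - ifelse(self_r > thr,
                                if (cfg$dc_weighted) self_r else 1, 0)
  }
  out <- array(0, d)
  out[mask] <- pmax(dc, 0)
  metric_map(out, "DC", mask, bold$voxel_size_mm,
             provenance = list(r_threshold = thr,
                               weighted = cfg$dc_weighted))
}

#' Normalize a metric map by its mask mean
#'
#' Divides by the mean over the gray-matter mask, so the normalized map has
#' mask-mean 1 (the `mReHo` / `mDC` convention).
#'
#' @param map a [metric_map()] of kind ReHo or DC.
#' @param mask logical 3D mask; defaults to the map's own mask.
#' @return A [metric_map()] of the normalized kind.
#' @export
normalize_by_mask_mean <- function(map, mask = map$mask) {
  stopifnot(inherits(map, "metric_map"))
  mu <- mean(map$values[mask])
  if (!is.finite(mu) || mu <= 0)
    stop("mask mean must be positive (got ", format(mu), ")")
  kind <- switch(map$kind, ReHo = "mReHo", DC = "mDC", "other")
  metric_map(map$values / mu, kind, map$mask, map$voxel_size_mm,
             provenance = c(map$provenance, list(mask_mean = mu)))
}

#' Post-minus-pre change map
#'
#' @param post,pre [metric_map()]s of the same kind and mask (normalized and
#'   smoothed).
#' @return A [metric_map()] of kind `"change"`.
#' @export
change_map <- function(post, pre) {
  stopifnot(inherits(post, "metric_map"), inherits(pre, "metric_map"))
  if (!identical(post$kind, pre$kind))
    stop("kind mismatch: ", post$kind, " vs ", pre$kind)
  if (!identical(post$mask, pre$mask)) stop("mask mismatch")
  metric_map(post$values - pre$values, "change", post$mask,
             post$voxel_size_mm,
             provenance = list(source_kind = post$kind))
}
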
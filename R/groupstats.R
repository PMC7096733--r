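# Voxelwise group statistics on change maps: repeated-measures one-way ANOVA
# across the three stimulation conditions, Gaussian-random-field cluster-level
# correction, pairwise paired t tests and Bonferroni control.

#' Assemble a panel of per-subject, per-condition change maps
#'
#' @param maps nested list `maps[[subject]][[condition]]` of change
#'   [metric_map()]s on a common grid and mask.
#' @return A `change_panel`: array `data` (n subjects x k conditions x V
#'   voxels), `subjects`, `conditions`, `mask`, `dims`, `voxel_size_mm`.
#' @export
change_panel <- function(maps) {
  subjects <- names(maps)
  conditions <- names(maps[[1]])
  if (is.null(subjects) || is.null(conditions))
    stop("`maps` must be a named nested list [subject][condition]")
  first <- maps[[1]][[1]]
  dims <- dim(first$values)
  mask <- first$mask
  n <- length(subjects); k <- length(conditions)
  dat <- array(NA_real_, c(n, k, prod(dims)))
  for (i in seq_len(n)) {
    if (!identical(sort(names(maps[[i]])), sort(conditions)))
      stop("incomplete panel: subject ", subjects[i], " is missing conditions")
    for (j in seq_len(k)) {
      m <- maps[[i]][[conditions[j]]]
      if (!identical(dim(m$values), dims) || !identical(m$mask, mask))
        stop("panel maps must share one grid and mask")
      dat[i, j, ] <- as.vector(m$values)
    }
  }
  structure(list(data = dat, subjects = subjects, conditions = conditions,
                 mask = mask, dims = dims,
                 voxel_size_mm = first$voxel_size_mm),
            class = "change_panel")
}

# panel from a plain n x k x V array (used by simulations and tests)
panel_from_array <- function(dat, mask, voxel_size_mm = 3,
                             subjects = NULL, conditions = NULL) {
  n <- dim(dat)[1]; k <- dim(dat)[2]
  structure(list(data = dat,
                 subjects = subjects %||% subject_ids(n),
                 conditions = conditions %||% conditions()[seq_len(k)],
                 mask = mask, dims = dim(mask),
                 voxel_size_mm = rep_len(voxel_size_mm, 3L)),
            class = "change_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Voxelwise one-way ANOVA map across conditions
#'
#' Within-subject (repeated-measures) by default: per voxel the two-way
#' subject-by-condition decomposition without replication gives
#' `F = MS_condition / MS_error` with `df = (k - 1, (k - 1)(n - 1))`. With
#' `within_subject = FALSE` the conditions are treated as independent groups
#' (`df = (k - 1, n k - k)`), provided for sensitivity analysis.
#'
#' @param panel a [change_panel()].
#' @param within_subject use the repeated-measures decomposition (default).
#' @return A [stat_map()] of F values. Voxels with zero error variance are
#'   flagged via a message and carry `F = Inf`.
#' @export
rm_anova_map <- function(panel, within_subject = TRUE) {
  stopifnot(inherits(panel, "change_panel"))
  n <- dim(panel$data)[1]; k <- dim(panel$data)[2]
  if (k < 2) stop("need at least 2 conditions")
  if (n < 3) stop("need at least 3 subjects")
  mask_v <- as.vector(panel$mask)
  A <- panel$data[, , mask_v, drop = FALSE]
  Vm <- dim(A)[3]
  cond_means <- apply(A, c(2, 3), mean)           # k x V
  grand <- colMeans(cond_means)                    # V
  ss_cond <- n * colSums(sweep(cond_means, 2L, grand)^2)
  ss_tot <- apply(A, 3L, function(m) sum((m - mean(m))^2))
  if (within_subject) {
    subj_means <- apply(A, c(1, 3), mean)          # n x V
    ss_subj <- k * colSums(sweep(subj_means, 2L, grand)^2)
    ss_err <- pmax(ss_tot - ss_cond - ss_subj, 0)
    df <- c(k - 1, (k - 1) * (n - 1))
  } else {
    ss_err <- pmax(ss_tot - ss_cond, 0)
    df <- c(k - 1, n * k - k)
  }
  ms_cond <- ss_cond / df[1]
  ms_err <- ss_err / df[2]
  f <- ifelse(ms_err > 0, ms_cond / ms_err,
              ifelse(ms_cond > 0, Inf, 0))
  if (any(is.infinite(f)))
    message("rm_anova_map: ", sum(is.infinite(f)),
            " voxel(s) with zero error variance (F = Inf)")
  out <- array(0, panel$dims)
  out[mask_v] <- f
  stat_map(out, df = df, mask = panel$mask, stat = "F",
           voxel_size_mm = panel$voxel_size_mm)
}

#' Paired t test between two condition vectors
#'
#' `d = a - b`, `t = mean(d) / (sd(d) / sqrt(n))`, two-tailed p with
#' `df = n - 1`. A degenerate zero-variance difference is flagged:
#' identical inputs give `t = 0, p = 1`; a constant nonzero difference gives
#' a signed infinite t with p = 0.
#'
#' @param a,b equal-length per-subject values, paired by position.
#' @return List: `t`, `p`, `mean_diff`, `sd_diff`, `n`, `df`, `degenerate`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  n <- length(a)
  if (n < 2) stop("need n >= 2 pairs")
  d <- a - b
  md <- mean(d); sdd <- stats::sd(d)
  # "essentially constant" guard (same criterion as stats::t.test)
  if (sdd / sqrt(n) < 10 * .Machine$double.eps * abs(md)) sdd <- 0
  if (sdd == 0) {
    t <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
    return(list(t = t, p = p, mean_diff = md, sd_diff = 0, n = n,
                df = n - 1, degenerate = TRUE))
  }
  t <- md / (sdd / sqrt(n))
  list(t = t, p = 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE),
       mean_diff = md, sd_diff = sdd, n = n, df = n - 1, degenerate = FALSE)
}

#' Paired t statistic from printed summary statistics
#'
#' Reproduces a reported t value from a printed mean difference, SD of the
#' differences, and sample size: `t = mean_diff / (sd_diff / sqrt(n))`
#' (report to 2 decimals).
#'
#' @param mean_diff mean of the paired differences.
#' @param sd_diff SD of the paired differences (> 0).
#' @param n number of pairs (>= 2).
#' @return The t statistic (unrounded).
#' @export
t_from_summary <- function(mean_diff, sd_diff, n) {
  if (n < 2) stop("need n >= 2")
  if (sd_diff <= 0) stop("`sd_diff` must be > 0")
  mean_diff / (sd_diff / sqrt(n))
}

#' Bonferroni-corrected alpha
#'
#' @param alpha family-wise level (default 0.05).
#' @param m number of comparisons (default 15: 5 regions x 3 condition
#'   pairs).
#' @return `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 15) {
  if (m < 1) stop("`m` must be >= 1")
  alpha / m
}

#' Estimate per-axis smoothness (FWHM) from residual maps
#'
#' Residuals are standardized per voxel (divided by their root mean square
#' across maps); the variance of the normalized spatial first differences
#' along each axis is inverted through the Gaussian autocorrelation
#' `E[(u(x+d) - u(x))^2] = 2 (1 - exp(-d^2 / (4 sigma^2)))` to give sigma and
#' hence FWHM in mm. Estimates are floored at the voxel size.
#'
#' @param residuals list of >= 2 residual 3D arrays on a common grid.
#' @param mask logical 3D mask.
#' @param voxel_size_mm per-axis voxel size in mm.
#' @return Numeric length-3 vector of FWHM estimates (mm).
#' @export
estimate_fwhm <- function(residuals, mask, voxel_size_mm = 3) {
  if (length(residuals) < 2) stop("need at least 2 residual maps")
  vs <- rep_len(voxel_size_mm, 3L)
  d <- dim(mask)
  R <- vapply(residuals, as.vector, numeric(prod(d)))   # V x m
  rms <- sqrt(rowMeans(R^2))
  ok <- rms > 0
  U <- R
  U[ok, ] <- R[ok, ] / rms[ok]
  fwhm <- numeric(3)
  for (ax in 1:3) {
    off <- c(0L, 0L, 0L); off[ax] <- 1L
    mask_pair <- mask & array(as.logical(shift3d(array(as.numeric(mask), d),
                                                 off)), d)
    pv <- which(as.vector(mask_pair) & ok)
    if (length(pv) == 0) { fwhm[ax] <- vs[ax]; next }
    lin_nb <- pv + c(1L, d[1], d[1] * d[2])[ax]
    dd <- U[lin_nb, , drop = FALSE] - U[pv, , drop = FALSE]
    m2 <- mean(dd^2)
    if (m2 >= 2 || m2 <= 0) { fwhm[ax] <- vs[ax]; next }
    sigma2 <- vs[ax]^2 / (-4 * log(1 - m2 / 2))
    fwhm[ax] <- max(2 * sqrt(2 * log(2)) * sqrt(sigma2), vs[ax])
  }
  fwhm
}

#' Cluster table with Gaussian-random-field correction
#'
#' Thresholds the statistic map at the voxel-level p, forms clusters by face
#' connectivity (configurable), and assigns each cluster a family-wise
#' corrected p from stationary Gaussian-field theory: the expected cluster
#' count comes from the field's Euler-characteristic density at the
#' (Gaussian-equivalent) threshold, and the extent tail uses the standard
#' exponential form in resel units,
#' `P(extent >= s) = exp(-beta s^(2/3))` with
#' `beta = (Gamma(5/2) E[m] / E[N])^(2/3)`; the corrected p is
#' `1 - exp(-E[m] P(extent >= s))`.
#'
#' @param stat a [stat_map()] (F or t).
#' @param mask logical 3D analysis mask.
#' @param fwhm per-axis smoothness in mm (from [estimate_fwhm()]).
#' @param voxel_p voxel-forming threshold (uncorrected p).
#' @param cluster_p cluster-level family-wise threshold.
#' @param connectivity 6 (faces, default), 18 or 26.
#' @return A data frame (possibly empty): peak world coordinates, extent in
#'   voxels and mm^3, peak statistic, peak uncorrected p, corrected p,
#'   `surviving` flag. Sorted by extent, largest first.
#' @export
grf_cluster_table <- function(stat, mask, fwhm, voxel_p = 0.001,
                              cluster_p = 0.05, connectivity = 6) {
  stopifnot(inherits(stat, "stat_map"))
  p <- stat_p_values(stat)
  supra <- (p < voxel_p) & mask
  empty <- data.frame(peak_x_mm = numeric(0), peak_y_mm = numeric(0),
                      peak_z_mm = numeric(0), extent_vox = integer(0),
                      extent_mm3 = numeric(0), peak_stat = numeric(0),
                      peak_p = numeric(0), corrected_p = numeric(0),
                      surviving = logical(0))
  if (!any(supra)) return(empty)
  lab <- label_clusters(supra, connectivity)
  vs <- stat$voxel_size_mm
  S <- sum(mask)
  u <- stats::qnorm(1 - voxel_p)
  resels <- S * prod(vs / pmax(fwhm, vs))
  rho3 <- (4 * log(2))^(3 / 2) / (2 * pi)^2 * (u^2 - 1) * exp(-u^2 / 2)
  e_m <- max(resels * rho3, .Machine$double.eps)
  e_n <- S * stats::pnorm(u, lower.tail = FALSE)
  beta <- (gamma(5 / 2) * e_m / e_n)^(2 / 3)
  rows <- lapply(seq_len(max(lab)), function(l) {
    vox <- which(lab == l)
    ext <- length(vox)
    peak <- vox[which.max(stat$values[vox])]
    ijk <- index_to_ijk(peak, dim(mask))[1, ]
    p_ext <- exp(-beta * ext^(2 / 3))
    p_corr <- 1 - exp(-e_m * p_ext)
    data.frame(peak_x_mm = voxel_to_world(ijk, vs)[1],
               peak_y_mm = voxel_to_world(ijk, vs)[2],
               peak_z_mm = voxel_to_world(ijk, vs)[3],
               extent_vox = ext, extent_mm3 = ext * prod(vs),
               peak_stat = stat$values[peak], peak_p = p[peak],
               corrected_p = p_corr, surviving = p_corr < cluster_p)
  })
  out <- do.call(rbind, rows)
  out[order(-out$extent_vox), , drop = FALSE]
}

#' Permutation null of the maximal cluster extent
#'
#' Independent within-subject permutation of condition labels; per
#' permutation the ANOVA F map is recomputed, thresholded at the voxel p, and
#' the maximal cluster extent recorded. The 95th percentile is the
#' permutation-based cluster-extent threshold, an assumption-free cross-check
#' of the Gaussian-field corrected table.
#'
#' @param panel a [change_panel()].
#' @param voxel_p voxel-forming threshold.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param connectivity cluster-forming connectivity.
#' @return Integer vector of maximal extents (voxels), length `n_perm`.
#' @export
permutation_max_extents <- function(panel, voxel_p = 0.001, n_perm = 500,
                                    seed = 0, connectivity = 6) {
  stopifnot(inherits(panel, "change_panel"))
  local_seed(seed)
  n <- dim(panel$data)[1]; k <- dim(panel$data)[2]
  vapply(seq_len(n_perm), function(i) {
    perm <- panel
    for (s in seq_len(n))
      perm$data[s, , ] <- panel$data[s, sample.int(k), ]
    f <- rm_anova_map(perm)
    p <- stat_p_values(f)
    supra <- (p < voxel_p) & panel$mask
    if (!any(supra)) return(0L)
    lab <- label_clusters(supra, connectivity)
    max(tabulate(lab[lab > 0L]))
  }, integer(1))
}

#' Extract per-subject, per-condition values at a voxel
#'
#' @param panel a [change_panel()].
#' @param voxel 1-based voxel indices (length 3), inside the mask.
#' @return n x k matrix, rows = subjects, columns = conditions.
#' @export
extract_values <- function(panel, voxel) {
  stopifnot(inherits(panel, "change_panel"))
  voxel <- as.integer(round(voxel))
  if (any(voxel < 1L) || any(voxel > panel$dims) ||
      !panel$mask[voxel[1], voxel[2], voxel[3]])
    stop("voxel lies outside the analysis mask")
  lin <- ijk_to_index(matrix(voxel, 1), panel$dims)
  out <- panel$data[, , lin]
  dimnames(out) <- list(panel$subjects, panel$conditions)
  out
}
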
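scalar_panel <- function(dat) {
  # n x k matrix of per-subject condition values on a 1-voxel grid
  panel_from_array(array(dat, c(dim(dat), 1)), mask = array(TRUE, c(1, 1, 1)))
}

test_that("the repeated-measures F map matches aov on scalar data", {
  set.seed(17)
  dat <- matrix(rnorm(9, mean = rep(c(0, 0.5, 1), each = 3)), 3, 3,
                byrow = FALSE)
  f <- rm_anova_map(scalar_panel(dat))
  df_long <- data.frame(y = as.vector(dat),
                        subj = factor(rep(1:3, 3)),
                        cond = factor(rep(1:3, each = 3)))
  oracle <- summary(stats::aov(y ~ cond + subj, data = df_long))[[1]]
  expect_equal(f$values[1, 1, 1], oracle["cond", "F value"],
               tolerance = 1e-10)
  expect_identical(f$df, c(2, 4))
  # between-groups variant against one-way aov
  fb <- rm_anova_map(scalar_panel(dat), within_subject = FALSE)
  oracle_b <- summary(stats::aov(y ~ cond, data = df_long))[[1]]
  expect_equal(fb$values[1, 1, 1], oracle_b["cond", "F value"],
               tolerance = 1e-10)
})

test_that("identical conditions give F = 0 and k = 2 reduces to paired t^2", {
  set.seed(18)
  base <- rnorm(5)
  same <- cbind(base, base, base)
  expect_equal(rm_anova_map(scalar_panel(same))$values[1, 1, 1], 0)
  # k = 2: F = t^2 voxelwise
  n <- 8; V <- 30
  dat <- array(rnorm(n * 2 * V), c(n, 2, V))
  mask <- array(TRUE, c(5, 6, 1))
  pan <- panel_from_array(dat, mask, conditions = c("High", "Sham"))
  f <- rm_anova_map(pan)
  t2 <- vapply(seq_len(V), function(v)
    paired_t(dat[, 1, v], dat[, 2, v])$t^2, numeric(1))
  expect_equal(f$values[mask], t2, tolerance = 1e-8)
})

test_that("paired t matches t.test and the printed summary reproduction", {
  set.seed(19)
  a <- rnorm(12); b <- rnorm(12)
  res <- paired_t(a, b)
  tt <- stats::t.test(a, b, paired = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  expect_equal(paired_t(b, a)$t, -res$t)
  expect_equal(paired_t(b, a)$p, res$p)
  same <- paired_t(a, a)
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_true(same$degenerate)
  shift <- paired_t(a + 1, a)
  expect_identical(shift$t, Inf)
  # printed cerebellar ReHo High-vs-Sham row: 0.22 +/- 0.29, n = 31 -> 4.22
  expect_equal(round(t_from_summary(0.22, 0.29, 31), 2), 4.22)
  expect_equal(t_from_summary(0, 1, 10), 0)
  expect_equal(t_from_summary(1, 1, 4), 2)
  expect_error(t_from_summary(1, 0, 10), "sd_diff")
  expect_error(t_from_summary(1, 1, 1), "n >= 2")
})

test_that("Bonferroni correction divides the family-wise level", {
  expect_equal(round(bonferroni_alpha(0.05, 15), 4), 0.0033)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.10, 4), 0.025)
  expect_error(bonferroni_alpha(0.05, 0), "m")
})

test_that("smoothness estimation recovers the kernel width", {
  d <- c(14, 14, 10)
  mask <- array(TRUE, d)
  gen <- function(fwhm, seed) {
    set.seed(seed)
    a <- array(rnorm(prod(d)), d)
    if (fwhm > 0)
      a <- rehodc:::smooth3d(a, rep(rehodc:::fwhm_to_sigma(fwhm) / 3, 3))
    a
  }
  white <- lapply(1:10, function(i) gen(0, i))
  fw_white <- estimate_fwhm(white, mask, 3)
  expect_true(all(abs(fw_white - 3) / 3 <= 0.2))
  sm6 <- lapply(1:10, function(i) gen(6, 100 + i))
  fw6 <- estimate_fwhm(sm6, mask, 3)
  expect_true(all(fw6 >= 5 & fw6 <= 7))
  sm9 <- lapply(1:10, function(i) gen(9, 200 + i))
  fw9 <- estimate_fwhm(sm9, mask, 3)
  expect_true(all(fw_white <= fw6 & fw6 <= fw9))
  expect_error(estimate_fwhm(white[1], mask, 3), "at least 2")
})

test_that("GRF cluster inference is calibrated on null smooth fields", {
  d <- c(14, 14, 10)
  cfg <- small_cfg(n_subjects = 2)
  mask <- make_mask(cfg)
  sigma <- rehodc:::fwhm_to_sigma(6) / 3
  set.seed(20)
  fields <- lapply(1:200, function(i) {
    a <- rehodc:::smooth3d(array(rnorm(prod(d)), d), rep(sigma, 3))
    a / sd(a[mask])
  })
  fw <- estimate_fwhm(fields[1:20], mask, 3)
  hits <- vapply(fields, function(fld) {
    sm <- stat_map(fld, df = 1e6, mask = mask, stat = "t")
    ct <- grf_cluster_table(sm, mask, fw, voxel_p = 0.001, cluster_p = 0.05)
    nrow(ct) > 0 && any(ct$surviving)
  }, logical(1))
  expect_lte(mean(hits), 0.10)
})

test_that("cluster tables report structure faithfully", {
  d <- c(10, 10, 8)
  mask <- array(TRUE, d)
  vals <- array(0, d)
  vals[3:5, 3:5, 3:4] <- 10           # one strong block
  vals[8, 8, 6] <- 8.5                # an isolated suprathreshold voxel
  sm <- stat_map(vals, df = c(2, 60), mask = mask, stat = "F")
  ct <- grf_cluster_table(sm, mask, fwhm = c(6, 6, 6), voxel_p = 0.001)
  expect_identical(nrow(ct), 2L)
  expect_identical(ct$extent_vox, c(18L, 1L))
  expect_true(all(ct$extent_mm3 == ct$extent_vox * 27))
  # peaks lie inside their clusters
  expect_true(ct$peak_x_mm[1] %in% c(6, 9, 12))
  expect_identical(ct$peak_x_mm[2], (8 - 1) * 3)
  # a lone voxel is far less likely to survive than the block
  expect_gt(ct$corrected_p[2], ct$corrected_p[1])
  # empty result when nothing is suprathreshold
  sm0 <- stat_map(array(0, d), df = c(2, 60), mask = mask, stat = "F")
  expect_identical(nrow(grf_cluster_table(sm0, mask, c(6, 6, 6))), 0L)
})

test_that("GRF surviving clusters agree with a permutation null", {
  coh <- strong_cohort()
  mask <- coh$truth$mask
  pan <- coh$ReHo
  f <- rm_anova_map(pan)
  fw <- estimate_fwhm(panel_residual_maps(pan), mask, 3)
  ct <- grf_cluster_table(f, mask, fw, voxel_p = 0.001, cluster_p = 0.05)
  null_ext <- permutation_max_extents(pan, voxel_p = 0.001, n_perm = 300,
                                      seed = 42)
  thr <- unname(stats::quantile(null_ext, 0.95))
  surviving_perm <- ct$extent_vox > thr
  expect_identical(ct$surviving, surviving_perm)
  expect_gte(sum(ct$surviving), 1)     # the injected effect is found
})

test_that("value extraction is exact and consistent with the paired test", {
  n <- 6
  dat <- array(rnorm(n * 3 * 8), c(n, 3, 8))
  dat[, , 5] <- matrix(seq_len(n * 3), n, 3)      # known values at voxel 5
  mask <- array(TRUE, c(2, 2, 2))
  pan <- panel_from_array(dat, mask)
  vox <- rehodc:::index_to_ijk(5L, c(2, 2, 2))[1, ]
  vals <- extract_values(pan, vox)
  expect_equal(unname(vals), matrix(seq_len(n * 3), n, 3))
  # round-trips through TSV
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(vals, path, sep = "\t", quote = FALSE)
  back <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE))
  expect_equal(unname(back), unname(vals))
  expect_error(extract_values(pan, c(50, 1, 1)), "outside")
  # peak extraction reproduces the paired t at that voxel
  coh <- strong_cohort()
  f <- rm_anova_map(coh$ReHo)
  pk <- rehodc:::index_to_ijk(which.max(f$values), dim(f$values))[1, ]
  pv <- extract_values(coh$ReHo, pk)
  j <- coh$ReHo$conditions
  res <- paired_t(pv[, "High"], pv[, "Sham"])
  lin <- rehodc:::ijk_to_index(matrix(pk, 1), dim(f$values))
  direct <- paired_t(coh$ReHo$data[, match("High", j), lin],
                     coh$ReHo$data[, match("Sham", j), lin])
  expect_equal(res$t, direct$t)
})

test_that("null-cohort ANOVA p-values are uniform over the mask", {
  coh <- null_cohort()
  f <- rm_anova_map(coh$ReHo)
  # neighboring voxels share smooth noise, which invalidates the nominal KS
  # level on the pooled set; sample a lattice wider than the noise FWHM so
  # the draws are approximately independent
  sel <- coh$truth$mask & lattice_mask(dim(f$values))
  p <- stat_p_values(f)[sel]
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
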
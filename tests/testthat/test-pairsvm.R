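random_panel <- function(n = 31, V = 40, seed = 23, k = 3) {
  set.seed(seed)
  mask <- array(TRUE, c(V, 1, 1))
  panel_from_array(array(rnorm(n * k * V), c(n, k, V)), mask)
}

full_feature_mask <- function(panel) {
  # all-mask feature selection via a permissive threshold on a random F map
  f <- rm_anova_map(panel)
  feature_mask_from_f(f, panel$mask, p_thresh = 1)
}

test_that("feature masks follow the F-map threshold contract", {
  pan <- random_panel()
  f <- rm_anova_map(pan)
  fm_all <- feature_mask_from_f(f, pan$mask, p_thresh = 1)
  expect_identical(length(fm_all$indices), sum(pan$mask))
  zero <- stat_map(array(0, pan$dims), df = c(2, 60), mask = pan$mask,
                   stat = "F")
  expect_error(feature_mask_from_f(zero, pan$mask, 0.05), "no voxel")
  # null cohort: about 5% of mask voxels selected (spatial dependence noted)
  coh <- null_cohort()
  fnull <- rm_anova_map(coh$ReHo)
  fm <- feature_mask_from_f(fnull, coh$truth$mask, 0.05)
  frac <- length(fm$indices) / sum(coh$truth$mask)
  expect_gt(frac, 0.01); expect_lt(frac, 0.12)
})

test_that("PAIR datasets implement the signed-difference grouping", {
  pan <- random_panel(n = 31)
  fm <- full_feature_mask(pan)
  ds <- build_pair_dataset(pan, c("High", "Sham"), fm, seed = 31)
  expect_identical(sort(as.integer(table(ds$group))), c(15L, 16L))
  expect_identical(c(sum(ds$y == -1), sum(ds$y == 1)), c(16L, 15L))
  # group A rows are the raw High-minus-Sham difference, B rows negated
  jx <- match("High", pan$conditions); jy <- match("Sham", pan$conditions)
  raw <- pan$data[, jx, fm$indices] - pan$data[, jy, fm$indices]
  a1 <- which(ds$group == "A")[1]; b1 <- which(ds$group == "B")[1]
  expect_equal(ds$x[a1, ], raw[a1, ])
  expect_equal(ds$x[b1, ], -raw[b1, ])
  # reversing the contrast with the same split negates samples
  ds_rev <- build_pair_dataset(pan, c("Sham", "High"), fm, seed = 31)
  expect_equal(ds_rev$x, -ds$x)
  expect_identical(ds_rev$y, ds$y)
  # determinism
  ds2 <- build_pair_dataset(pan, c("High", "Sham"), fm, seed = 31)
  expect_identical(ds$group, ds2$group)
  expect_error(build_pair_dataset(random_panel(n = 3), c("High", "Sham"),
                                  full_feature_mask(random_panel(n = 3)),
                                  seed = 1),
               "at least 4")
})

test_that("the linear SVM attains the closed-form max-margin solution", {
  x <- rbind(c(1, 0), c(-1, 0))
  m <- train_linear_svm(x, c(1, -1), C = 1e4)
  expect_equal(m$w, c(1, 0), tolerance = 1e-6)
  expect_equal(m$b, 0, tolerance = 1e-6)
  # duplicating training points leaves the (hard-margin) decision unchanged
  set.seed(24)
  x2 <- matrix(rnorm(20), 10, 2)
  y2 <- rep(c(1, -1), 5)
  x2[y2 == 1, 1] <- x2[y2 == 1, 1] + 3      # separable
  m1 <- train_linear_svm(x2, y2, C = 100, tol = 1e-6)
  m2 <- train_linear_svm(rbind(x2, x2), c(y2, y2), C = 100, tol = 1e-6)
  expect_equal(svm_decision(m1, x2), svm_decision(m2, x2), tolerance = 1e-4)
  expect_error(train_linear_svm(x2, rep(1, 10)), "single class")
})

test_that("SVM decision values agree with an independent QP solution", {
  skip_if_not_installed("kernlab")
  set.seed(25)
  n <- 10; p <- 3
  x <- matrix(rnorm(n * p), n, p)
  y <- rep(c(1, -1), each = n / 2)
  x[y == 1, 1] <- x[y == 1, 1] + 4        # separable
  C <- 1
  m <- train_linear_svm(x, y, C = C, tol = 1e-8)
  # dual soft-margin QP: min 1/2 a' Q a - 1' a, 0 <= a <= C, y' a = 0
  Q <- (y %*% t(y)) * (x %*% t(x))
  sol <- kernlab::ipop(c = -rep(1, n), H = Q, A = matrix(y, 1), b = 0,
                       l = rep(0, n), u = rep(C, n), r = 0, sigf = 9)
  alpha <- kernlab::primal(sol)
  w_qp <- colSums(alpha * y * x)
  sv <- which(alpha > 1e-6 & alpha < C - 1e-6)
  b_qp <- mean(y[sv] - x[sv, , drop = FALSE] %*% w_qp)
  expect_equal(svm_decision(m, x), drop(x %*% w_qp + b_qp),
               tolerance = 1e-4)
})

test_that("split-half validation is deterministic and chance-level on nulls", {
  coh <- null_cohort()
  f <- rm_anova_map(coh$ReHo)
  # chance-level calibration requires selection-independent features: use
  # the whole mask (selecting on the same cohort's F map is circular and
  # inflates null accuracy; see the double-dipping test below)
  fm <- feature_mask_from_f(f, coh$truth$mask, p_thresh = 1)
  ds <- build_pair_dataset(coh$ReHo, c("High", "Sham"), fm, seed = 3)
  cv <- split_half_cv(ds, repeats = 50, seed = 4)
  expect_gte(cv$mean_accuracy, 0.35)
  expect_lte(cv$mean_accuracy, 0.65)
  expect_true(all(cv$accuracies >= 0 & cv$accuracies <= 1))
  expect_equal(cv$mean_accuracy, mean(cv$accuracies))
  # repeats = 1 equals one manual stratified split at the same seed
  cv1 <- split_half_cv(ds, repeats = 1, seed = 9)
  set.seed(9)
  idx_a <- which(ds$group == "A"); idx_b <- which(ds$group == "B")
  tr <- c(sample(idx_a, floor(length(idx_a) / 2)),
          sample(idx_b, floor(length(idx_b) / 2)))
  te <- setdiff(seq_along(ds$y), tr)
  model <- train_linear_svm(ds$x[tr, ], ds$y[tr], C = 1)
  acc <- mean(sign(svm_decision(model, ds$x[te, ])) == ds$y[te])
  expect_equal(cv1$accuracies, acc)
})

test_that("PAIR predictions are antisymmetric and feature-order invariant", {
  coh <- strong_cohort()
  f <- rm_anova_map(coh$ReHo)
  fm <- feature_mask_from_f(f, coh$truth$mask, 0.05)
  ds <- build_pair_dataset(coh$ReHo, c("High", "Sham"), fm, seed = 6)
  cv <- split_half_cv(ds, repeats = 10, seed = 7)
  # negate all samples and labels
  neg <- ds; neg$x <- -ds$x; neg$y <- -ds$y
  neg$group <- ifelse(ds$group == "A", "B", "A")
  cv_neg <- split_half_cv(neg, repeats = 10, seed = 7)
  expect_equal(cv_neg$accuracies, cv$accuracies, tolerance = 1e-10)
  # permute features: accuracies unchanged, weights permuted along
  perm <- sample(ncol(ds$x))
  dsp <- ds; dsp$x <- ds$x[, perm]
  cv_p <- split_half_cv(dsp, repeats = 10, seed = 7)
  expect_equal(cv_p$accuracies, cv$accuracies, tolerance = 1e-10)
  expect_equal(cv_p$mean_weights, cv$mean_weights[perm], tolerance = 1e-6)
})

test_that("null accuracy over many datasets is centered on chance", {
  # dataset-level accuracy varies widely at small n; the mean over
  # independent null datasets must sit near 0.5
  set.seed(27)
  n <- 8
  datasets <- lapply(1:12, function(i) {
    diffs <- matrix(rnorm(n * 300), n, 300)
    grp <- sample(rep(c("A", "B"), each = n / 2))
    x <- diffs; x[grp == "B", ] <- -x[grp == "B", ]
    structure(list(x = x, y = ifelse(grp == "A", 1, -1), group = grp,
                   subjects = as.character(1:n), contrast = c("X", "Y"),
                   seed = 0),
              class = "pair_dataset")
  })
  accs <- vapply(seq_along(datasets), function(i)
    split_half_cv(datasets[[i]], repeats = 10,
                  seed = 700 + i)$mean_accuracy, numeric(1))
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})

test_that("same-cohort feature selection inflates null accuracy (double dipping)", {
  # the F-map threshold picks voxels whose condition differences are
  # consistent across subjects by chance; the PAIR construction then
  # separates the groups far above their selection-free accuracy even with
  # no real effect -- the circularity the clean per-fold selection avoids
  coh <- null_cohort()
  f <- rm_anova_map(coh$ReHo)
  fm_circular <- feature_mask_from_f(f, coh$truth$mask, 0.05)
  fm_clean <- feature_mask_from_f(f, coh$truth$mask, p_thresh = 1)
  acc <- function(fm, seed) {
    ds <- build_pair_dataset(coh$ReHo, c("High", "Sham"), fm, seed = 3)
    split_half_cv(ds, repeats = 20, seed = seed)$mean_accuracy
  }
  acc_circ <- acc(fm_circular, 4)
  acc_clean <- acc(fm_clean, 4)
  expect_gt(acc_circ, 0.55)
  expect_gt(acc_circ, acc_clean + 0.1)
})

test_that("accuracy grows with the injected amplitude", {
  series <- amplitude_series()
  accs <- vapply(series, function(s) {
    f <- rm_anova_map(s$ReHo)
    fm <- feature_mask_from_f(f, s$truth$mask, 0.05)
    ds <- build_pair_dataset(s$ReHo, c("High", "Sham"), fm, seed = 8)
    split_half_cv(ds, repeats = 20, seed = 9)$mean_accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("weight back-projection round-trips and finds the truth region", {
  coh <- strong_cohort()
  f <- rm_anova_map(coh$ReHo)
  fm <- feature_mask_from_f(f, coh$truth$mask, 0.05)
  zero_map <- project_weights(rep(0, length(fm$indices)), fm,
                              coh$truth$mask)
  expect_true(all(zero_map$values == 0))
  ds <- build_pair_dataset(coh$ReHo, c("High", "Sham"), fm, seed = 10)
  cv <- split_half_cv(ds, repeats = 20, seed = 11)
  wmap <- project_weights(cv, fm, coh$truth$mask)
  expect_equal(wmap$values[fm$indices], unname(cv$mean_weights))
  expect_error(project_weights(1:3, fm, coh$truth$mask), "does not match")
  # top-decile |weight| voxels are enriched in the ground-truth region
  w <- abs(cv$mean_weights)
  top <- fm$indices[w >= stats::quantile(w, 0.9)]
  truth_idx <- which(coh$truth$effect_mask)
  q <- sum(top %in% truth_idx)
  m_ <- length(truth_idx); n_ <- sum(coh$truth$mask) - m_; k_ <- length(top)
  p_enrich <- stats::phyper(q - 1, m_, n_, k_, lower.tail = FALSE)
  expect_lt(p_enrich, 0.01)
})

test_that("single-voxel AUC follows the rank-sum identity", {
  expect_equal(voxel_auc(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(voxel_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  # enumerate the 4 pairs of A = (3,1), B = (2,0): 3 concordant of 4
  expect_equal(voxel_auc(c(3, 1), c(2, 0)), 0.75)
  expect_error(voxel_auc(numeric(0), 1), "nonempty")
  set.seed(26)
  a <- rnorm(20, 1); b <- rnorm(20)
  w <- stats::wilcox.test(a, b, exact = FALSE)
  expect_equal(voxel_auc(a, b), unname(w$statistic) / (20 * 20),
               tolerance = 1e-12)
})
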
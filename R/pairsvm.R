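# PAIR SVM condition discrimination: feature selection on the uncorrected F
# map, signed-difference sample construction (the PAIR scheme), linear
# soft-margin SVM, repeated split-half validation, weight back-projection and
# single-voxel ROC/AUC.

#' Feature mask from an uncorrected F map
#'
#' Selects in-mask voxels with uncorrected `p < p_thresh`. Voxels with an
#' infinite F (zero error variance) are excluded with a message.
#'
#' @param fmap a [stat_map()] of F values with df set.
#' @param mask logical 3D gray-matter mask.
#' @param p_thresh uncorrected threshold (default 0.05).
#' @return A `feature_mask`: ordered linear voxel `indices`, `threshold`,
#'   `dims`.
#' @export
feature_mask_from_f <- function(fmap, mask, p_thresh = 0.05) {
  stopifnot(inherits(fmap, "stat_map"))
  p <- stat_p_values(fmap)
  sel <- (p < p_thresh) & mask
  inf_f <- is.infinite(fmap$values) & sel
  if (any(inf_f)) {
    message("feature_mask_from_f: excluding ", sum(inf_f),
            " voxel(s) with infinite F")
    sel <- sel & !inf_f
  }
  idx <- which(sel)
  if (length(idx) == 0L)
    stop("no voxel passes p < ", p_thresh,
         "; relax the threshold or check the F map")
  structure(list(indices = idx, threshold = p_thresh, dims = dim(mask)),
            class = "feature_mask")
}

#' Build a PAIR dataset for one condition contrast
#'
#' Subjects are randomly split into group A (size `floor(n/2)`) and group B
#' (size `ceiling(n/2)`). Group A samples are the condX-minus-condY change
#' differences (label +1); group B samples are the reversed difference
#' condY-minus-condX (label -1). Features are restricted to the feature
#' mask.
#'
#' @param panel a [change_panel()] containing both conditions.
#' @param contrast ordered condition pair, e.g. `c("High", "Sham")`.
#' @param fm a [feature_mask_from_f()] result.
#' @param seed RNG seed for the group split.
#' @return A `pair_dataset`: `x` (n x d matrix), `y` (+1/-1), `group`
#'   ("A"/"B" per subject), `subjects`, `contrast`, `seed`.
#' @export
build_pair_dataset <- function(panel, contrast, fm, seed = 0) {
  stopifnot(inherits(panel, "change_panel"), inherits(fm, "feature_mask"))
  if (!all(contrast %in% panel$conditions))
    stop("contrast conditions not present in the panel")
  n <- dim(panel$data)[1]
  if (n < 4) stop("need at least 4 subjects for split-half training")
  jx <- match(contrast[1], panel$conditions)
  jy <- match(contrast[2], panel$conditions)
  diff <- panel$data[, jx, fm$indices, drop = TRUE] -
    panel$data[, jy, fm$indices, drop = TRUE]
  diff <- matrix(diff, nrow = n)
  local_seed(seed)
  perm <- sample.int(n)
  a_idx <- perm[seq_len(floor(n / 2))]
  group <- rep("B", n); group[a_idx] <- "A"
  x <- diff
  x[group == "B", ] <- -x[group == "B", , drop = FALSE]
  y <- ifelse(group == "A", 1, -1)
  structure(list(x = x, y = y, group = group, subjects = panel$subjects,
                 contrast = contrast, seed = seed),
            class = "pair_dataset")
}

#' Train a linear soft-margin SVM
#'
#' Solves the linear-kernel soft-margin dual (sequential minimal
#' optimization) to the given KKT tolerance and returns the primal weight
#' vector and bias, with signs aligned so the decision value `w x + b` is
#' positive for the +1 class.
#'
#' @param x n x d training matrix.
#' @param y labels, +1 / -1 (both classes must be present).
#' @param C soft-margin cost (default 1).
#' @param tol solver KKT tolerance.
#' @return An `svm_model`: `w`, `b`, `C`, `tol`.
#' @export
train_linear_svm <- function(x, y, C = 1, tol = 1e-3) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    stop("training set contains a single class")
  fit <- e1071::svm(x, factor(y, levels = c(1, -1)), kernel = "linear",
                    cost = C, tolerance = tol, scale = FALSE)
  w <- unname(drop(crossprod(fit$SV, fit$coefs)))
  b <- -fit$rho
  # align sign with the +1 class: libsvm orients by first training label
  f <- drop(x %*% w + b)
  if (sum(sign(f) == y) < sum(sign(-f) == y)) {
    w <- -w; b <- -b
  }
  structure(list(w = w, b = b, C = C, tol = tol), class = "svm_model")
}

#' Decision values of a linear SVM
#'
#' @param model an `svm_model` from [train_linear_svm()].
#' @param x matrix of samples.
#' @return Numeric decision values `x w + b`; the predicted label is their
#'   sign.
#' @export
svm_decision <- function(model, x) {
  drop(as.matrix(x) %*% model$w + model$b)
}

#' Repeated split-half cross-validation of a PAIR dataset
#'
#' Per repetition, a stratified half/half split of subjects: `floor(n_g / 2)`
#' subjects are drawn from each group for training and the rest are held
#' out. The model is trained on one half and the held-out accuracy recorded,
#' together with the weight vector. A repetition whose training half is
#' single-class is redrawn (logged), never silently skipped.
#'
#' @param ds a [build_pair_dataset()] result.
#' @param repeats number of random splits (default 100).
#' @param C soft-margin cost.
#' @param seed RNG seed.
#' @param tol solver tolerance.
#' @param absolute_weights average absolute rather than signed weights.
#' @return A `cv_result`: `accuracies` (length `repeats`), `mean_accuracy`,
#'   `mean_weights`, `repeats`, `seed`.
#' @export
split_half_cv <- function(ds, repeats = 100, C = 1, seed = 0, tol = 1e-3,
                          absolute_weights = FALSE) {
  stopifnot(inherits(ds, "pair_dataset"))
  local_seed(seed)
  idx_a <- which(ds$group == "A")
  idx_b <- which(ds$group == "B")
  acc <- numeric(repeats)
  wsum <- 0
  for (r in seq_len(repeats)) {
    for (attempt in 1:100) {
      tr <- c(sample(idx_a, floor(length(idx_a) / 2)),
              sample(idx_b, floor(length(idx_b) / 2)))
      if (length(unique(ds$y[tr])) == 2) break
      message("split_half_cv: single-class training half redrawn")
    }
    te <- setdiff(seq_along(ds$y), tr)
    model <- train_linear_svm(ds$x[tr, , drop = FALSE], ds$y[tr], C, tol)
    pred <- sign(svm_decision(model, ds$x[te, , drop = FALSE]))
    acc[r] <- mean(pred == ds$y[te])
    wsum <- wsum + if (absolute_weights) abs(model$w) else model$w
  }
  structure(list(accuracies = acc, mean_accuracy = mean(acc),
                 mean_weights = wsum / repeats, repeats = repeats,
                 seed = seed),
            class = "cv_result")
}

#' Back-project SVM weights to a brain map
#'
#' Writes the (mean) weight vector back to its voxel positions; zero
#' elsewhere.
#'
#' @param cv a `cv_result` (or a bare numeric weight vector).
#' @param fm the [feature_mask_from_f()] the weights were trained on.
#' @param mask logical 3D mask for the output map.
#' @param voxel_size_mm per-axis voxel size.
#' @return A [metric_map()] of kind `"weight"`.
#' @export
project_weights <- function(cv, fm, mask, voxel_size_mm = 3) {
  w <- if (inherits(cv, "cv_result")) cv$mean_weights else as.numeric(cv)
  if (length(w) != length(fm$indices))
    stop("weight length (", length(w), ") does not match feature mask (",
         length(fm$indices), ")")
  vals <- array(0, fm$dims)
  vals[fm$indices] <- w
  metric_map(vals, "weight", mask, voxel_size_mm,
             provenance = list(n_features = length(w)))
}

#' Single-voxel ROC AUC between two conditions
#'
#' Mann-Whitney rank-sum identity treating condition A as positive; ties
#' contribute 1/2.
#'
#' @param values_a,values_b per-subject scalars for the two conditions.
#' @return AUC in `[0, 1]`.
#' @export
voxel_auc <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (na == 0 || nb == 0) stop("both value lists must be nonempty")
  r <- rank(c(values_a, values_b))
  (sum(r[seq_len(na)]) - na * (na + 1) / 2) / (na * nb)
}
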
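#' Conditional-Gaussian imputation of missing coordinates
#'
#' Maximum-likelihood re-estimation of the missing block of an aligned pose
#' under the model Gaussian:
#' `x_m = mu_m + C_{m,in} C_{in,in}^{-1} (x_in - mu_in)`
#' with the mean and regularized covariance partitioned into missing and
#' inlier coordinates. (The printed source formulas disagree on the block
#' subscripts; the standard Gaussian conditional mean — the unique maximizer
#' of the conditional density, fixed by dimensional consistency — is
#' implemented.) Solved via Cholesky factorization; inlier coordinates are
#' returned unchanged.
#'
#' @param pose `n_bp x d` matrix in the model frame, `NA` rows = missing.
#' @param model a [shape_model()].
#' @param C optional precomputed [model_covariance()] (loop optimization).
#' @return complete `n_bp x d` matrix.
#' @export
conditional_impute <- function(pose, model, C = NULL) {
  d <- model$d
  obs <- stats::complete.cases(pose)
  if (!any(obs)) ssm_stop("empty inlier set", "ssmpose_data_error")
  if (all(obs)) return(pose)
  x <- vec_pose(pose)
  ci_in <- coord_idx(which(obs), d)
  ci_m <- coord_idx(which(!obs), d)
  if (is.null(C)) C <- model_covariance(model)
  U <- chol(C[ci_in, ci_in, drop = FALSE])
  dev <- x[ci_in] - model$mu[ci_in]
  # C_{m,in} C_{in,in}^{-1} dev via two triangular solves
  w <- backsolve(U, backsolve(U, dev, transpose = TRUE))
  x[ci_m] <- model$mu[ci_m] + C[ci_m, ci_in, drop = FALSE] %*% w
  unvec_pose(x, d)
}

# Alternating rigid-alignment / shape-estimation fit of one pose onto the
# model (the classic active-shape-model loop). Aligning inliers straight onto
# the mean pose lets the pose's own deformation (scale ~ sqrt(sum(lambda)/p)
# per coordinate) leak into the rigid fit whenever only a subset of points is
# observed; re-targeting the alignment at the model's predicted shape
# (mu + V b_hat) removes that leakage in 2-3 iterations. Returns NULL when
# the points cannot be aligned.
asm_fit_pose <- function(pose, model, points, n_iter = 3L, C = NULL) {
  if (length(points) < 3L) return(NULL)
  if (is.null(C)) C <- model_covariance(model)
  mu_mat <- mean_pose_matrix(model)
  target <- mu_mat
  tf <- NULL; completed <- NULL
  for (it in seq_len(max(1L, n_iter))) {
    al <- tryCatch(
      procrustes_align(pose[points, , drop = FALSE],
                       target[points, , drop = FALSE],
                       policy = model$alignment_policy, min_common = 3L),
      ssmpose_alignment_error = function(e) NULL)
    if (is.null(al)) return(NULL)
    full <- matrix(NA_real_, model$n_bp, model$d)
    full[points, ] <- al$aligned
    completed <- conditional_impute(full, model, C = C)
    b_hat <- shape_parameters(completed, model)
    target <- mu_mat + unvec_pose(as.vector(model$eigenposes %*% b_hat),
                                  model$d)
    tf <- al$transform
  }
  xv <- vec_pose(completed)
  md2 <- md2_subset(xv, model$mu, C, points, model$d)
  list(md2 = md2, transform = tf, completed = completed, b = b_hat)
}

#' Shape parameters of an aligned pose
#'
#' Projection of the mean-centred pose onto the eigenposes:
#' `b = V' (x - mu)`.
#'
#' @param pose complete `n_bp x d` matrix in the model frame, or a vectorised
#'   pose.
#' @param model a [shape_model()].
#' @return numeric vector of length `r`.
#' @export
shape_parameters <- function(pose, model) {
  x <- if (is.matrix(pose)) vec_pose(pose) else pose
  as.vector(crossprod(model$eigenposes, x - model$mu))
}

#' Model-based reconstruction of a dataset
#'
#' Per frame: rigidly align the inlier landmarks into the model frame,
#' impute every missing landmark (original gaps plus re-masked outliers)
#' with [conditional_impute()], and map the completed pose back through the
#' inverse transform so the output lives in the original coordinate frame.
#' Alignment and imputation are alternated for `n_refine` iterations with
#' the alignment re-targeted at the model's predicted shape, which stops the
#' pose's own deformation from biasing the rigid fit on partial point sets.
#' Observed inlier coordinates are copied through bit-for-bit. Frames whose
#' outlier status is `"exhausted"` (or with too few inliers to align) are
#' returned unchanged and listed.
#'
#' @param dataset the original (contaminated) [pose_dataset()].
#' @param model a [shape_model()].
#' @param report optional `outlier_report` from [detect_outliers()]; its
#'   flags are added to the missing set.
#' @param min_common minimum inliers for alignment.
#' @param n_refine align/impute refinement iterations (default 3).
#' @return list with `recovered` (a complete [pose_dataset()] in the original
#'   frame), `skipped` (frame indices left unchanged), `imputed_mask`
#'   (`n x n_bp`, which landmarks were re-estimated).
#' @export
reconstruct_dataset <- function(dataset, model, report = NULL,
                                min_common = NULL, n_refine = 3L) {
  d <- dataset$d
  if (is.null(min_common)) min_common <- default_min_common(d)
  miss <- dataset$mask
  if (!is.null(report)) miss <- miss | report$flags
  exhausted <- if (!is.null(report)) report$status == "exhausted"
               else rep(FALSE, dataset$n_frames)
  C <- model_covariance(model)
  out <- dataset$coords
  skipped <- integer(0)
  for (i in seq_len(dataset$n_frames)) {
    mi <- miss[i, ]
    if (!any(mi)) next                       # nothing to re-estimate
    if (exhausted[i] || sum(!mi) < min_common) {
      skipped <- c(skipped, i)
      next
    }
    pose <- matrix(dataset$coords[i, , ], dataset$n_bp, d)
    fitp <- asm_fit_pose(pose, model, which(!mi), n_iter = n_refine, C = C)
    if (is.null(fitp)) { skipped <- c(skipped, i); next }
    back <- apply_transform(fitp$completed, invert_transform(fitp$transform))
    out[i, mi, ] <- back[mi, ]
    # inlier coordinates keep their original values bit-for-bit
  }
  keep_mask <- matrix(FALSE, dataset$n_frames, dataset$n_bp)
  if (length(skipped)) keep_mask[skipped, ] <- dataset$mask[skipped, ]
  recovered <- pose_dataset(out, mask = keep_mask,
                            point_names = dataset$point_names,
                            frame_ids = dataset$frame_ids)
  list(recovered = recovered, skipped = skipped,
       imputed_mask = miss & !keep_mask)
}

#' Full unsupervised pose-recovery pipeline
#'
#' One call chaining the three stages: [fit_ssm()] (robust SSM estimation),
#' [detect_outliers()] (flag and re-mask outlier landmarks) and
#' [reconstruct_dataset()] (conditional-Gaussian re-estimation of all
#' missing/outlier landmarks, reported in the original frame). Identical
#' code path for 2D and 3D data.
#'
#' @param dataset a [pose_dataset()].
#' @param cfg a [fit_config()].
#' @return object of class `ssm_recovery`: `recovered` dataset, `fit`
#'   (the `ssm_fit`), `outliers` (the `outlier_report`), `skipped`,
#'   `imputed_mask`.
#' @export
recover_poses <- function(dataset, cfg = fit_config()) {
  fit <- fit_ssm(dataset, cfg)
  rep_out <- detect_outliers(fit$aligned, fit$model, alpha = cfg$alpha,
                             max_removals = cfg$max_removals,
                             min_points = cfg$min_common, ok = fit$ok,
                             realign = cfg$realign_after_removal)
  rec <- reconstruct_dataset(dataset, fit$model, rep_out,
                             min_common = cfg$min_common)
  structure(list(recovered = rec$recovered, fit = fit, outliers = rep_out,
                 skipped = rec$skipped, imputed_mask = rec$imputed_mask),
            class = "ssm_recovery")
}

#' @export
print.ssm_recovery <- function(x, ...) {
  cat(sprintf("<ssm_recovery> %d frames; %d landmarks re-estimated; %d frames skipped\n",
              x$recovered$n_frames, sum(x$imputed_mask), length(x$skipped)))
  invisible(x)
}
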
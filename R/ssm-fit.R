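#' Fitting configuration
#'
#' Bundles every tunable of the unsupervised SSM estimator. Defaults
#' reproduce the reference protocol: 100 RANSAC iterations scoring a random
#' complete reference pose on a fresh 50% subsample, neighbour threshold
#' auto-tuned to the first quartile of sampled pairwise aligned distances,
#' KNN pre-imputation with k = 5, OGK covariance, and PPCA regularization
#' keeping r = 5 eigenposes.
#'
#' @param n_ransac_iter RANSAC iterations (default 100).
#' @param subsample_frac fraction of poses scored per iteration (default 0.5).
#' @param neighbour_threshold `"auto"` (first quartile of sampled pairwise
#'   aligned distances) or a numeric distance.
#' @param n_pairs_quartile pairs sampled when auto-tuning the threshold.
#' @param knn_k neighbours averaged by the pre-imputation step.
#' @param rank_policy `"fixed_r"` or `"variance_fraction"`.
#' @param r number of eigenposes (`fixed_r`) or the cumulative variance
#'   target in (0, 1) (`variance_fraction`).
#' @param alpha chi-square significance level for outlier detection.
#' @param alignment_policy `"rigid"` (default) or `"similarity"`.
#' @param min_common minimum commonly observed points for alignment
#'   (default 3 in 2D, 4 in 3D; resolved at fit time when `NULL`).
#' @param max_removals cap on greedy point removals per pose (default
#'   `n_bp - min_common`, resolved at fit time).
#' @param realign_after_removal re-align each candidate sub-pose to the mean
#'   during greedy outlier removal (default `TRUE`; see
#'   [detect_outlier_points()]).
#' @param refine_to_mean run one extra alignment pass onto the estimated mean
#'   pose after the reference-based pass (default `TRUE`). Consensus
#'   averaging about the *reference* is biased toward the reference's own
#'   noise realization (an O(sigma) bias that does not vanish with n);
#'   re-centering the consensus on the estimated mean removes it.
#' @param mean_estimator `"ransac"` (consensus reference) or `"naive"`
#'   (random complete reference; the mu-naive ablation).
#' @param cov_estimator `"ogk"` or `"sample"` (the C-naive ablation).
#' @param seed integer; all randomness (reference candidates, subsampling,
#'   threshold pair sampling) flows from this one seed.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(n_ransac_iter = 100L, subsample_frac = 0.5,
                       neighbour_threshold = "auto", n_pairs_quartile = 2000L,
                       knn_k = 5L, rank_policy = c("fixed_r", "variance_fraction"),
                       r = 5L, alpha = 0.01,
                       alignment_policy = c("rigid", "similarity"),
                       min_common = NULL, max_removals = NULL,
                       realign_after_removal = TRUE, refine_to_mean = TRUE,
                       mean_estimator = c("ransac", "naive"),
                       cov_estimator = c("ogk", "sample"), seed = 1L) {
  rank_policy <- match.arg(rank_policy)
  stopifnot(n_ransac_iter >= 1L, subsample_frac > 0, subsample_frac <= 1,
            knn_k >= 1L, alpha > 0, alpha < 1)
  if (rank_policy == "variance_fraction" && (r <= 0 || r >= 1))
    ssm_stop("variance_fraction policy needs r in (0,1)", "ssmpose_config_error")
  structure(list(n_ransac_iter = as.integer(n_ransac_iter),
                 subsample_frac = subsample_frac,
                 neighbour_threshold = neighbour_threshold,
                 n_pairs_quartile = as.integer(n_pairs_quartile),
                 knn_k = as.integer(knn_k), rank_policy = rank_policy, r = r,
                 alpha = alpha, alignment_policy = match.arg(alignment_policy),
                 min_common = min_common, max_removals = max_removals,
                 realign_after_removal = realign_after_removal,
                 refine_to_mean = refine_to_mean,
                 mean_estimator = match.arg(mean_estimator),
                 cov_estimator = match.arg(cov_estimator),
                 seed = as.integer(seed)),
            class = "fit_config")
}

resolve_threshold <- function(dataset, cfg) {
  if (identical(cfg$neighbour_threshold, "auto"))
    pairwise_distance_quartile(dataset, cfg$n_pairs_quartile, seed = cfg$seed,
                               policy = cfg$alignment_policy)
  else as.numeric(cfg$neighbour_threshold)
}

#' RANSAC selection of the reference pose
#'
#' Repeats `cfg$n_ransac_iter` times: draw a complete pose uniformly at
#' random as candidate reference, draw a fresh subsample of
#' `ceiling(subsample_frac * n)` poses, Procrustes-align the subsample to the
#' candidate and score the candidate by its number of neighbour poses
#' (aligned residual below `threshold`). The best-scoring candidate wins;
#' ties break by smaller mean residual, then lower frame index.
#'
#' @param dataset a [pose_dataset()] with at least 10 frames and at least one
#'   complete pose.
#' @param cfg a [fit_config()].
#' @param threshold neighbour threshold; default resolves `"auto"` from `cfg`.
#' @return list with `reference` (frame index), `score`, `threshold`.
#' @export
select_reference_pose <- function(dataset, cfg = fit_config(), threshold = NULL) {
  n <- dataset$n_frames
  if (n < 10L) ssm_stop("dataset too small (< 10 poses)", "ssmpose_data_error")
  complete <- complete_frames(dataset)
  if (!length(complete))
    ssm_stop("no complete pose available as reference", "ssmpose_data_error")
  if (is.null(threshold)) threshold <- resolve_threshold(dataset, cfg)
  m <- ceiling(cfg$subsample_frac * n)
  cube <- pose_cube(dataset)
  obs <- obs_matrix(dataset)
  min_common <- cfg$min_common %||% default_min_common(dataset$d)
  best <- list(score = -1L, mean_resid = Inf, idx = NA_integer_)
  with_seed(cfg$seed, {
    for (it in seq_len(cfg$n_ransac_iter)) {
      cand <- complete[sample.int(length(complete), 1L)]
      sub <- sample.int(n, m)
      ref <- cube[, , cand]
      res <- cpp_align_batch(cube[, , sub, drop = FALSE],
                             obs[, sub, drop = FALSE], ref,
                             rep(1L, dataset$n_bp), min_common,
                             cfg$alignment_policy == "similarity")
      resid <- res$residual
      score <- sum(resid < threshold, na.rm = TRUE)
      mres <- mean(resid, na.rm = TRUE)
      better <- score > best$score ||
        (score == best$score && (mres < best$mean_resid ||
          (mres == best$mean_resid && (is.na(best$idx) || cand < best$idx))))
      if (isTRUE(better)) best <- list(score = score, mean_resid = mres, idx = cand)
    }
  })
  list(reference = best$idx, score = best$score, threshold = threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Robust consensus estimate of the mean pose
#'
#' Aligns every pose to the RANSAC-selected reference and averages the
#' aligned poses coordinate-wise over observed entries. The average runs
#' over the consensus set — poses whose alignment residual is below the
#' neighbour threshold (plus the reference itself) — so poses that do not
#' belong to the dominant shape population cannot drag the mean. With
#' `cfg$mean_estimator = "naive"` the reference is instead a single random
#' complete pose and *all* aligned poses are averaged (the mu-naive
#' ablation). Unalignable poses (too few common points) are flagged, not
#' dropped.
#'
#' @inheritParams select_reference_pose
#' @return list with `mu` (vectorised mean pose), `aligned`
#'   (a [pose_dataset()] in the model frame), `transforms` (raw batch
#'   alignment result; see [frame_transform()]), `ok` (logical per frame),
#'   `reference`, `score`, `threshold`.
#' @export
estimate_mean_pose <- function(dataset, cfg = fit_config(), threshold = NULL) {
  if (cfg$mean_estimator == "ransac") {
    sel <- select_reference_pose(dataset, cfg, threshold)
  } else {
    complete <- complete_frames(dataset)
    if (!length(complete))
      ssm_stop("no complete pose available as reference", "ssmpose_data_error")
    ref_idx <- with_seed(cfg$seed, complete[sample.int(length(complete), 1L)])
    sel <- list(reference = ref_idx, score = NA_integer_,
                threshold = threshold %||% NA_real_)
  }
  min_common <- cfg$min_common %||% default_min_common(dataset$d)
  ref <- matrix(dataset$coords[sel$reference, , ], dataset$n_bp, dataset$d)
  al <- align_dataset(dataset, ref, rep(TRUE, dataset$n_bp),
                      policy = cfg$alignment_policy, min_common = min_common)
  consensus_mean <- function(al) {
    keep <- if (cfg$mean_estimator == "ransac" && is.finite(sel$threshold))
      which(al$ok == 1L & (al$residual < sel$threshold |
                             seq_along(al$ok) == sel$reference))
    else which(al$ok == 1L)
    m <- rowMeans(al$aligned[, , keep, drop = FALSE], na.rm = TRUE, dims = 2L)
    if (anyNA(m)) {      # coordinate never observed in the consensus set
      fallback <- rowMeans(al$aligned, na.rm = TRUE, dims = 2L)
      m[is.na(m)] <- fallback[is.na(m)]
    }
    m
  }
  mu_mat <- consensus_mean(al)
  # the mu-naive ablation is literally "mean of poses aligned to a random
  # complete reference": the re-centred refinement pass is part of the
  # robust-mean machinery being ablated, so it is skipped there
  if (isTRUE(cfg$refine_to_mean) && cfg$mean_estimator == "ransac") {
    al <- align_dataset(dataset, mu_mat, rep(TRUE, dataset$n_bp),
                        policy = cfg$alignment_policy, min_common = min_common)
    mu_mat <- consensus_mean(al)
  }
  aligned <- pose_dataset(cube_to_coords(al$aligned),
                          point_names = dataset$point_names,
                          frame_ids = dataset$frame_ids)
  list(mu = vec_pose(mu_mat), aligned = aligned, transforms = al,
       ok = al$ok == 1L, reference = sel$reference, score = sel$score,
       threshold = sel$threshold)
}

#' Per-frame transform from a batch alignment result
#'
#' @param transforms the `transforms` element of [estimate_mean_pose()] /
#'   [fit_ssm()] output.
#' @param i frame index.
#' @return a [rigid_transform()] mapping the original frame into the model
#'   frame, or `NULL` when the frame could not be aligned.
#' @export
frame_transform <- function(transforms, i) {
  if (transforms$ok[i] != 1L) return(NULL)
  d <- dim(transforms$rotation)[1]
  rigid_transform(matrix(transforms$rotation[, , i], d, d),
                  transforms$translation[i, ], transforms$scale[i])
}

#' K-nearest-neighbour pre-imputation
#'
#' For each pose with missing landmarks, every recovering pose (observed at
#' all of the target's missing positions) is rigidly aligned to the target on
#' their commonly observed points, ranked by RMS distance over those points,
#' and the nearest `k` are averaged at the missing positions. Observed
#' entries are never modified.
#'
#' @param aligned a [pose_dataset()] (poses already in a common frame).
#' @param k number of neighbours (default 5).
#' @param min_common minimum common points for candidate alignment.
#' @return a complete [pose_dataset()].
#' @export
knn_impute <- function(aligned, k = 5L, min_common = NULL) {
  if (is.null(min_common)) min_common <- default_min_common(aligned$d)
  res <- cpp_knn_impute(pose_cube(aligned), obs_matrix(aligned),
                        as.integer(k), as.integer(min_common))
  if (length(res$fail_pose))
    ssm_stop(sprintf("no recovering pose for frame %d, point '%s'",
                     res$fail_pose[1],
                     aligned$point_names[res$fail_point[1]]),
             "ssmpose_data_error")
  pose_dataset(cube_to_coords(res$coords), point_names = aligned$point_names,
               frame_ids = aligned$frame_ids)
}

#' Orthogonalized Gnanadesikan-Kettenring covariance
#'
#' Deterministic robust covariance estimate (Maronna-Zamar). Univariate
#' location/scale are median/MAD; pairwise covariances use the
#' Gnanadesikan-Kettenring identity `(s(X+Y)^2 - s(X-Y)^2) / 4`; the pairwise
#' matrix is orthogonalized by one eigendecomposition, robust scales are
#' re-estimated in the orthogonal basis and transformed back. A final hard
#' rejection step (squared robust distances beyond the scaled
#' `qchisq(beta, p)` cutoff) with a chi-square consistency factor brings the
#' clean-data estimate in line with the sample covariance.
#'
#' @param data complete numeric matrix, rows = observations.
#' @param n_orth orthogonalization iterations (default 1).
#' @param reweight apply the hard-rejection reweighting step (default TRUE).
#' @param beta retention quantile of the reweighting cutoff (default 0.9).
#' @return `p x p` symmetric positive definite matrix, with attributes
#'   `location` (robust centre) and `weights` (0/1 row weights).
#' @export
ogk_covariance <- function(data, n_orth = 1L, reweight = TRUE, beta = 0.9) {
  X <- as.matrix(data)
  if (anyNA(X)) ssm_stop("ogk_covariance needs complete data", "ssmpose_data_error")
  n <- nrow(X); p <- ncol(X)
  if (n <= 2L) ssm_stop("need n > 2 observations", "ssmpose_data_error")
  scale_fun <- function(v) {
    s <- mad(v)
    if (s <= 0) {
      warning("degenerate coordinate: zero MAD, flooring robust scale")
      s <- max(1e-10 * (max(abs(v - median(v))) + 1), 1e-300)
    }
    s
  }
  A <- diag(1, p)                     # accumulated back-transform
  Y <- X
  for (iter in seq_len(max(1L, n_orth))) {
    s <- apply(Y, 2L, scale_fun)
    Ys <- sweep(Y, 2L, s, `/`)
    U <- diag(1, p)
    if (p > 1L) {
      for (j in seq_len(p - 1L)) for (k in seq((j + 1L), p)) {
        sp <- mad(Ys[, j] + Ys[, k])
        sm <- mad(Ys[, j] - Ys[, k])
        U[j, k] <- U[k, j] <- (sp^2 - sm^2) / 4
      }
    }
    E <- eigen(U, symmetric = TRUE)$vectors
    A <- A %*% (diag(s, p) %*% E)
    Y <- Ys %*% E
  }
  sz <- apply(Y, 2L, scale_fun)
  mz <- apply(Y, 2L, median)
  loc <- as.vector(A %*% mz)
  C <- A %*% (t(A) * sz^2)            # A diag(sz^2) A'
  C <- (C + t(C)) / 2
  w <- rep(1, n)
  if (reweight) {
    d2 <- stats::mahalanobis(X, loc, C)
    cutoff <- qchisq(beta, p) * median(d2) / qchisq(0.5, p)
    w <- as.numeric(d2 <= cutoff)
    keep <- which(w == 1)
    if (length(keep) > max(p + 1L, 2L)) {
      loc <- colMeans(X[keep, , drop = FALSE])
      Xc <- sweep(X[keep, , drop = FALSE], 2L, loc)
      cf <- pchisq(qchisq(beta, p), p + 2L) / beta  # truncation consistency
      C <- crossprod(Xc) / (length(keep) * cf)
      C <- (C + t(C)) / 2
    }
  }
  attr(C, "location") <- loc
  attr(C, "weights") <- w
  C
}

#' PPCA regularization of a covariance matrix
#'
#' Keeps the top-`r` eigenpairs of `C` and replaces the remaining `p - r`
#' eigenvalues by their average `sigma2` (floored at a tiny fraction of
#' `trace(C)/p` so the regularized covariance is always full-rank SPD).
#' Under `rank_policy = "variance_fraction"`, `r` is the smallest integer
#' whose cumulative eigenvalue share reaches the target.
#'
#' @param C symmetric covariance matrix.
#' @param rank_policy `"fixed_r"` or `"variance_fraction"`.
#' @param r_or_frac integer rank, or variance target in (0, 1).
#' @return list with `eigenposes` (`p x r`), `eigenvalues` (length `r`),
#'   `sigma2`, `r`, `explained` (cumulative eigenvalue shares).
#' @export
ppca_regularize <- function(C, rank_policy = c("fixed_r", "variance_fraction"),
                            r_or_frac = 5L) {
  rank_policy <- match.arg(rank_policy)
  C <- as.matrix(C)
  p <- ncol(C)
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    ssm_stop("C must be symmetric", "ssmpose_model_error")
  eig <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vals <- eig$values
  explained <- cumsum(vals) / sum(vals)
  r <- if (rank_policy == "fixed_r") as.integer(r_or_frac)
       else which(explained >= r_or_frac)[1]
  if (r >= p)
    ssm_stop("r must leave at least one noise direction (r < p)",
             "ssmpose_model_error")
  sigma2 <- mean(vals[(r + 1L):p])
  sigma2 <- max(sigma2, 1e-10 * sum(abs(vals)) / p)
  sigma2 <- min(sigma2, vals[r])      # preserve eigenvalue >= sigma2
  list(eigenposes = eig$vectors[, seq_len(r), drop = FALSE],
       eigenvalues = vals[seq_len(r)], sigma2 = sigma2, r = r,
       explained = explained)
}

#' Unsupervised SSM estimation
#'
#' Full robust fitting chain: RANSAC consensus mean pose (Procrustes
#' alignment of every pose to the winning reference), KNN pre-imputation of
#' missing landmarks, OGK robust covariance of the mean-centred aligned
#' poses, and PPCA regularization into a full-rank Gaussian shape model.
#'
#' @param dataset a [pose_dataset()].
#' @param cfg a [fit_config()].
#' @return object of class `ssm_fit`: `model` (a [shape_model()]),
#'   `aligned` (dataset in the model frame), `transforms` (batch alignment;
#'   see [frame_transform()]), `ok` (alignable frames) and `report`
#'   (reference index, threshold, alignment failures, rank, explained
#'   variance curve).
#' @export
fit_ssm <- function(dataset, cfg = fit_config()) {
  est <- estimate_mean_pose(dataset, cfg)
  ok <- est$ok
  if (!any(ok)) ssm_stop("no pose could be aligned", "ssmpose_data_error")
  aligned_ok <- est$aligned[which(ok)]
  imputed <- if (any(aligned_ok$mask)) knn_impute(aligned_ok, cfg$knn_k,
                                                  cfg$min_common)
             else aligned_ok
  Xc <- sweep(dataset_matrix(imputed), 2L, est$mu)
  C <- if (cfg$cov_estimator == "ogk") ogk_covariance(Xc)
       else {
         Cs <- stats::cov(Xc)
         attr(Cs, "location") <- colMeans(Xc)
         Cs
       }
  reg <- ppca_regularize(C, cfg$rank_policy, cfg$r)
  model <- shape_model(est$mu, reg$eigenposes, reg$eigenvalues, reg$sigma2,
                       dataset$d, cfg$alignment_policy,
                       point_names = dataset$point_names)
  report <- list(reference = est$reference, reference_score = est$score,
                 neighbour_threshold = est$threshold,
                 n_frames = dataset$n_frames, n_unaligned = sum(!ok),
                 unaligned_frames = which(!ok), r = reg$r,
                 sigma2 = reg$sigma2, explained_variance = reg$explained,
                 mean_estimator = cfg$mean_estimator,
                 cov_estimator = cfg$cov_estimator, seed = cfg$seed)
  structure(list(model = model, aligned = est$aligned,
                 transforms = est$transforms, ok = ok, report = report,
                 cfg = cfg),
            class = "ssm_fit")
}

#' @export
print.ssm_fit <- function(x, ...) {
  cat(sprintf("<ssm_fit> reference frame %d (score %s), threshold %.4g\n",
              x$report$reference, format(x$report$reference_score),
              x$report$neighbour_threshold))
  print(x$model)
  invisible(x)
}
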
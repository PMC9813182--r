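#' Root-mean-square error between two datasets
#'
#' Square root of the mean squared coordinate difference. Coordinates masked
#' in either dataset are always excluded (RMSE is undefined for missing
#' entries); `scope = "masked_only"` instead restricts to the entries of
#' `mask_only`, e.g. the planted contamination mask of a simulation.
#'
#' @param a,b [pose_dataset()]s (or plain coordinate arrays) of identical
#'   dimensions.
#' @param scope `"all"` or `"masked_only"`.
#' @param mask_only `n x n_bp` logical matrix selecting the landmarks to
#'   compare when `scope = "masked_only"`.
#' @return nonnegative scalar.
#' @export
rmse <- function(a, b, scope = c("all", "masked_only"), mask_only = NULL) {
  scope <- match.arg(scope)
  ca <- if (inherits(a, "pose_dataset")) a$coords else a
  cb <- if (inherits(b, "pose_dataset")) b$coords else b
  if (!identical(dim(ca), dim(cb)))
    ssm_stop("datasets have different dimensions", "ssmpose_data_error")
  keep <- !apply(!is.finite(ca) | !is.finite(cb), c(1, 2), any)
  if (scope == "masked_only") {
    if (is.null(mask_only))
      ssm_stop("scope = 'masked_only' needs mask_only", "ssmpose_data_error")
    keep <- keep & mask_only
  }
  if (!any(keep)) ssm_stop("no comparable entries", "ssmpose_data_error")
  d <- dim(ca)[3]
  sq <- 0; cnt <- 0
  for (k in seq_len(d)) {
    diffk <- (ca[, , k] - cb[, , k])[keep]
    sq <- sq + sum(diffk^2); cnt <- cnt + length(diffk)
  }
  sqrt(sq / cnt)
}

# rotate eigenpose columns (vectorised, point-major) by a spatial rotation
rotate_eigenposes <- function(P, R) {
  d <- ncol(R)
  apply(P, 2L, function(v) vec_pose(unvec_pose(v, d) %*% R))
}

# greedy best-|dot| assignment between columns; returns est column index for
# each reference column
greedy_match <- function(P_ref, P_est) {
  r <- ncol(P_ref)
  A <- abs(crossprod(P_ref, P_est))
  assign <- integer(r)
  used <- rep(FALSE, r)
  for (step in seq_len(r)) {
    A_mask <- A
    A_mask[, used] <- -Inf
    A_mask[assign != 0L, ] <- -Inf
    ij <- which(A_mask == max(A_mask), arr.ind = TRUE)[1, ]
    assign[ij[1]] <- ij[2]
    used[ij[2]] <- TRUE
  }
  assign
}

#' Scalar products between true and estimated eigenposes
#'
#' `SP_j = |p_j' phat_j|` after (optionally) rotating the estimated
#' eigenposes into the ground-truth frame via the rigid rotation that aligns
#' the estimated mean pose onto the true mean shape — without this step the
#' comparison is meaningless under nuisance rotation. Columns are matched by
#' eigenvalue rank by default, or by greedy best-|dot| assignment
#' (automatically when adjacent eigenvalues of `eigenvalues` differ by less
#' than 5%, where subspace rotation would deflate rank-matched SP
#' spuriously).
#'
#' @param P_true,P_est orthonormal `p x r` eigenpose matrices.
#' @param mean_true true mean shape (`n_bp x d` matrix) and
#' @param mean_est estimated mean pose (matrix or vectorised); both needed to
#'   map frames. Omit when both sets already share a frame.
#' @param match `"rank"` or `"greedy"`.
#' @param eigenvalues optional estimated eigenvalues used to auto-switch to
#'   greedy matching near degeneracies.
#' @return numeric vector of `|SP|` values in `[0, 1]`, one per eigenpose.
#' @export
eigenpose_similarity <- function(P_true, P_est, mean_true = NULL,
                                 mean_est = NULL, match = c("rank", "greedy"),
                                 eigenvalues = NULL) {
  match <- match.arg(match)
  if (ncol(P_true) != ncol(P_est))
    ssm_stop("eigenpose sets have different column counts", "ssmpose_data_error")
  if (!is.null(mean_true) && !is.null(mean_est)) {
    d <- ncol(mean_true)
    mu_est <- if (is.matrix(mean_est)) mean_est else unvec_pose(mean_est, d)
    al <- procrustes_align(mu_est, mean_true, policy = "rigid")
    P_est <- rotate_eigenposes(P_est, al$transform$rotation)
  }
  if (match == "rank" && !is.null(eigenvalues) && length(eigenvalues) > 1) {
    gaps <- abs(diff(eigenvalues)) / pmax(abs(eigenvalues[-1]), 1e-12)
    if (any(gaps < 0.05)) match <- "greedy"
  }
  idx <- if (match == "greedy") greedy_match(P_true, P_est)
         else seq_len(ncol(P_true))
  pmin(1, abs(colSums(P_true * P_est[, idx, drop = FALSE])))
}

#' Correlation between true and estimated shape parameters
#'
#' Absolute Pearson correlation per matched eigenpose across poses (the sign
#' of an eigenvector is arbitrary, so `|rho|` is the meaningful quantity).
#'
#' @param b_true,b_est `n x r` shape-parameter matrices over the same poses.
#' @param pairs optional matching (est column per true column).
#' @return numeric vector of `|rho|` in `[0, 1]`.
#' @export
shape_param_correlation <- function(b_true, b_est, pairs = NULL) {
  if (is.null(pairs)) pairs <- seq_len(ncol(b_true))
  vapply(seq_len(ncol(b_true)), function(j) {
    r <- suppressWarnings(cor(b_true[, j], b_est[, pairs[j]]))
    if (is.na(r)) 0 else min(1, abs(r))
  }, numeric(1))
}

#' Ablated SSM fits
#'
#' The two naive baselines: `mu_naive` replaces the RANSAC consensus mean by
#' the plain mask-aware mean of poses aligned to one random complete
#' reference; `C_naive` replaces the OGK covariance by the maximum-likelihood
#' sample covariance. Everything else is identical to [fit_ssm()].
#'
#' @param dataset a [pose_dataset()].
#' @param cfg a [fit_config()].
#' @param ablation `"mu_naive"` or `"C_naive"`.
#' @return an `ssm_fit`.
#' @export
naive_fit <- function(dataset, cfg = fit_config(),
                      ablation = c("mu_naive", "C_naive")) {
  ablation <- match.arg(ablation)
  if (ablation == "mu_naive") cfg$mean_estimator <- "naive"
  else cfg$cov_estimator <- "sample"
  fit_ssm(dataset, cfg)
}

#' Resampling convergence of eigenpose estimation
#'
#' For each set size, draws `n_resamples` independent subsets, fits an SSM to
#' each and reports the mean and SD of all pairwise matched `|SP|` values
#' between the fitted eigenpose sets (estimates mapped into a common frame
#' through their mean poses). An expected value of 1 means identical
#' eigenposes across resamples.
#'
#' @param dataset a [pose_dataset()].
#' @param set_sizes integer vector of subset sizes.
#' @param n_resamples subsets per size (default 10).
#' @param cfg a [fit_config()]; per-fit seeds are derived from `cfg$seed`.
#' @return data frame: `size`, `mean_sp`, `sd_sp`, `n_pairs`.
#' @export
convergence_analysis <- function(dataset, set_sizes, n_resamples = 10L,
                                 cfg = fit_config()) {
  out <- lapply(set_sizes, function(sz) {
    if (sz > dataset$n_frames)
      ssm_stop("set size exceeds dataset size", "ssmpose_data_error")
    fits <- lapply(seq_len(n_resamples), function(rep) {
      sub_seed <- (cfg$seed + 104729L * rep + sz) %% .Machine$integer.max
      idx <- with_seed(sub_seed, sample.int(dataset$n_frames, sz))
      cfg_i <- cfg; cfg_i$seed <- sub_seed
      fit_ssm(dataset[idx], cfg_i)
    })
    sps <- c()
    for (a in seq_len(n_resamples - 1L)) for (b in seq((a + 1L), n_resamples)) {
      ma <- fits[[a]]$model; mb <- fits[[b]]$model
      sp <- eigenpose_similarity(ma$eigenposes, mb$eigenposes,
                                 mean_true = mean_pose_matrix(ma),
                                 mean_est = mean_pose_matrix(mb),
                                 match = "greedy")
      sps <- c(sps, mean(sp))
    }
    data.frame(size = sz, mean_sp = mean(sps), sd_sp = sd(sps),
               n_pairs = length(sps))
  })
  do.call(rbind, out)
}
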
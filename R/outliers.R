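#' Squared Mahalanobis distance to the shape model
#'
#' `MD^2 = (x - mu_s)' C_ss^{-1} (x - mu_s)` where the mean and regularized
#' covariance are marginalized to the coordinates of the retained points
#' (`d` coordinates per point). Solved through a Cholesky factor, never an
#' explicit inverse.
#'
#' @param x numeric vector over the subset's coordinates (model frame), or a
#'   full-length pose vector from which the subset is extracted.
#' @param model a [shape_model()].
#' @param subset integer indices of retained points (default all).
#' @return nonnegative scalar.
#' @export
mahalanobis_sq <- function(x, model, subset = seq_len(model$n_bp)) {
  if (!length(subset)) ssm_stop("empty subset", "ssmpose_model_error")
  ci <- coord_idx(sort(subset), model$d)
  C <- model_covariance(model)[ci, ci, drop = FALSE]
  xs <- if (length(x) == length(model$mu)) x[ci] else x
  if (length(xs) != length(ci))
    ssm_stop("x length matches neither the subset nor the full pose",
             "ssmpose_model_error")
  dev <- xs - model$mu[ci]
  U <- tryCatch(chol(C), error = function(e)
    ssm_stop("marginal model covariance is not SPD (violated model invariant)",
             "ssmpose_model_error"))
  sum(backsolve(U, dev, transpose = TRUE)^2)
}

#' Chi-square outlier threshold
#'
#' `(1 - alpha)` quantile of the chi-square distribution with
#' `d * n_points_retained` degrees of freedom. Recomputed at every greedy
#' removal step so the test df tracks the retained coordinates.
#'
#' @param n_points_retained number of retained landmarks.
#' @param d spatial dimensionality.
#' @param alpha significance level in (0, 1).
#' @return quantile threshold for MD^2.
#' @export
chi2_threshold <- function(n_points_retained, d, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1, n_points_retained >= 1, d >= 1)
  qchisq(1 - alpha, df = d * n_points_retained)
}

# Cholesky-based MD^2 for one pose on given point subset, using a
# precomputed dense covariance (avoids rebuilding model_covariance in loops).
md2_subset <- function(xvec, mu, Cfull, points, d) {
  ci <- coord_idx(points, d)
  dev <- xvec[ci] - mu[ci]
  U <- chol(Cfull[ci, ci, drop = FALSE])
  sum(backsolve(U, dev, transpose = TRUE)^2)
}

# Leave-one-out standardized residuals: predict each retained landmark from
# the other retained landmarks under the model Gaussian and return the
# squared Mahalanobis residual (df = d each) against the conditional
# covariance (Schur complement).
loo_point_z2 <- function(pose_aligned, mu, Cfull, retained, d) {
  vapply(seq_along(retained), function(j) {
    pt <- retained[j]; others <- retained[-j]
    ci <- coord_idx(pt, d); co <- coord_idx(others, d)
    U <- chol(Cfull[co, co, drop = FALSE])
    dev_o <- vec_pose(pose_aligned)[co] - mu[co]
    Cio <- Cfull[ci, co, drop = FALSE]
    w <- backsolve(U, backsolve(U, dev_o, transpose = TRUE))
    pred <- mu[ci] + as.vector(Cio %*% w)
    S <- Cfull[ci, ci] - Cio %*% backsolve(U, backsolve(U, t(Cio), transpose = TRUE))
    r <- vec_pose(pose_aligned)[ci] - pred
    sum(backsolve(chol((S + t(S)) / 2), r, transpose = TRUE)^2)
  }, numeric(1))
}

#' Greedy identification of outlier landmarks in one pose
#'
#' Tests the observed pose against the chi-square bound; while it exceeds the
#' bound, removes the point whose exclusion yields the smallest MD^2 of the
#' remaining sub-pose, re-adjusting the degrees of freedom after every
#' removal. Stops with status `"recovered"` when the sub-pose passes,
#' `"clean"` when the initial pose already passes, or `"exhausted"` when
#' removals would drop below the alignment minimum or `max_removals`.
#'
#' @param pose `n_bp x d` matrix in the model frame (`NA` rows = missing).
#' @param model a [shape_model()].
#' @param alpha significance level (default 0.01).
#' @param max_removals cap on removals (default `n_obs - min_points`).
#' @param min_points minimum retained points (default 3 in 2D, 4 in 3D).
#' @param realign re-estimate the rigid alignment of each candidate sub-pose
#'   onto the mean pose before computing its MD^2 (default `TRUE`). A pose
#'   whose alignment was dragged by its own outliers looks uniformly bad;
#'   re-aligning after exclusion lets the greedy step see which removal
#'   actually restores the pose, at the cost of one Procrustes fit per
#'   candidate.
#' @param verify_points after the greedy loop, predict each retained landmark
#'   from the others (leave-one-out conditional Gaussian) and remove
#'   landmarks whose standardized residual exceeds the `chi^2_d` bound
#'   (default `TRUE`). Runs only on poses already flagged by the global test,
#'   so the pose-level type-I rate is unchanged; it catches moderate outliers
#'   that the re-aligned global statistic can absorb when few points remain.
#' @return list with `outliers` (point indices), `status`, `md2_trace`
#'   (MD^2 tested at each iteration), `thresholds`, `retained`.
#' @export
detect_outlier_points <- function(pose, model, alpha = 0.01,
                                  max_removals = NULL, min_points = NULL,
                                  realign = TRUE, verify_points = TRUE) {
  d <- model$d
  if (is.null(min_points)) min_points <- default_min_common(d)
  obs <- which(stats::complete.cases(pose))
  if (length(obs) < min_points)
    return(list(outliers = integer(0), status = "exhausted",
                md2_trace = numeric(0), thresholds = numeric(0),
                retained = obs))
  if (is.null(max_removals)) max_removals <- length(obs) - min_points
  xvec <- vec_pose(pose)
  Cfull <- model_covariance(model)
  sub_md2 <- function(points) {
    if (realign) {
      fitp <- asm_fit_pose(pose, model, points, n_iter = 2L, C = Cfull)
      if (!is.null(fitp)) return(fitp$md2)
    }
    md2_subset(xvec, model$mu, Cfull, points, d)
  }
  retained <- obs
  removed <- integer(0)
  # A re-aligned MD^2 has ~ d*n - (d + d(d-1)/2) effective degrees of
  # freedom: the per-subset rigid fit absorbs the translation/rotation
  # dimensions (verified against simulation). Tests on the supplied
  # alignment keep the full d*n df.
  rigid_dof <- d + d * (d - 1L) / 2L
  thr_for <- function(n_pts, realigned) {
    df_pts <- if (realigned) max(1L, d * n_pts - rigid_dof) / d else n_pts
    chi2_threshold(df_pts, d, alpha)
  }
  # the initial test on a complete pose uses the supplied (fit-time)
  # alignment; a partially observed pose is re-fit first since its subset
  # alignment is already leakage-prone
  init_realigned <- realign && length(obs) < model$n_bp
  md2 <- if (init_realigned) sub_md2(retained)
         else md2_subset(xvec, model$mu, Cfull, retained, d)
  thr <- thr_for(length(retained), init_realigned)
  trace_md2 <- md2; trace_thr <- thr
  if (md2 <= thr)
    return(list(outliers = integer(0), status = "clean", md2_trace = trace_md2,
                thresholds = trace_thr, retained = retained))
  status <- "exhausted"
  while (length(removed) < max_removals && length(retained) > min_points) {
    md2_cand <- vapply(seq_along(retained), function(j)
      sub_md2(retained[-j]), numeric(1))
    j_best <- which.min(md2_cand)
    removed <- c(removed, retained[j_best])
    retained <- retained[-j_best]
    md2 <- md2_cand[j_best]
    thr <- thr_for(length(retained), realign)
    trace_md2 <- c(trace_md2, md2); trace_thr <- c(trace_thr, thr)
    if (md2 <= thr) { status <- "recovered"; break }
  }
  if (verify_points && realign && length(removed)) {
    z_thr <- qchisq(1 - alpha, df = d)
    while (length(retained) > min_points && length(removed) < max_removals) {
      fitp <- asm_fit_pose(pose, model, retained, n_iter = 2L, C = Cfull)
      if (is.null(fitp)) break
      z2 <- loo_point_z2(fitp$completed, model$mu, Cfull, retained, d)
      j_bad <- which.max(z2)
      if (z2[j_bad] <= z_thr) break
      removed <- c(removed, retained[j_bad])
      retained <- retained[-j_bad]
      md2 <- sub_md2(retained)
      thr <- thr_for(length(retained), realign)
      trace_md2 <- c(trace_md2, md2); trace_thr <- c(trace_thr, thr)
      status <- if (md2 <= thr) "recovered" else status
    }
  }
  list(outliers = removed, status = status, md2_trace = trace_md2,
       thresholds = trace_thr, retained = retained)
}

#' Dataset-level outlier detection
#'
#' Applies [detect_outlier_points()] to every alignable frame of a dataset in
#' the model frame and re-masks flagged landmarks (converted to missing) in
#' the returned working copy.
#'
#' @param aligned a [pose_dataset()] in the model frame (e.g. the `aligned`
#'   element of [fit_ssm()]).
#' @param model a [shape_model()].
#' @param alpha significance level (default 0.01).
#' @param max_removals,min_points,realign per-pose settings; see
#'   [detect_outlier_points()].
#' @param ok optional logical vector of alignable frames; others are reported
#'   as `"exhausted"` and skipped.
#' @return object of class `outlier_report`: `flags` (`n x n_bp` logical),
#'   `status` (per frame), `masked` (working copy with flags re-masked),
#'   `table` (long data frame: frame, iteration, point, md2, threshold,
#'   status).
#' @export
detect_outliers <- function(aligned, model, alpha = 0.01, max_removals = NULL,
                            min_points = NULL, ok = NULL, realign = TRUE) {
  n <- aligned$n_frames
  if (is.null(ok)) ok <- rep(TRUE, n)
  flags <- matrix(FALSE, n, aligned$n_bp)
  status <- character(n)
  rows <- vector("list", n)
  d <- model$d
  Cfull <- model_covariance(model)
  min_pts <- min_points %||% default_min_common(d)
  # fast path: full MD^2 of all complete frames in one Cholesky solve
  X <- dataset_matrix(aligned)
  comp <- which(!rowSums(aligned$mask) & ok)
  md2_full <- rep(NA_real_, n)
  if (length(comp)) {
    U <- chol(Cfull)
    devs <- backsolve(U, t(X[comp, , drop = FALSE]) - model$mu, transpose = TRUE)
    md2_full[comp] <- colSums(devs^2)
  }
  thr_full <- chi2_threshold(aligned$n_bp, d, alpha)
  for (i in seq_len(n)) {
    if (!ok[i]) { status[i] <- "exhausted"; next }
    if (i %in% comp && md2_full[i] <= thr_full) {
      status[i] <- "clean"
      next
    }
    p <- pose_at(aligned, i)
    det <- detect_outlier_points(p$coords, model, alpha, max_removals, min_pts,
                                 realign = realign)
    status[i] <- det$status
    flags[i, det$outliers] <- TRUE
    if (length(det$md2_trace))
      rows[[i]] <- data.frame(frame = aligned$frame_ids[i],
                              iteration = seq_along(det$md2_trace) - 1L,
                              point = c(NA_integer_, det$outliers)[
                                seq_along(det$md2_trace)],
                              md2 = det$md2_trace,
                              threshold = det$thresholds,
                              status = det$status)
  }
  masked <- aligned
  masked$mask <- aligned$mask | flags
  for (k in seq_len(aligned$d)) {
    slab <- masked$coords[, , k]
    slab[masked$mask] <- NA_real_
    masked$coords[, , k] <- slab
  }
  structure(list(flags = flags, status = status, masked = masked,
                 table = do.call(rbind, rows[!vapply(rows, is.null, TRUE)]),
                 alpha = alpha),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> %d frames: %d clean, %d recovered, %d exhausted; %d points flagged\n",
              length(x$status), sum(x$status == "clean"),
              sum(x$status == "recovered"), sum(x$status == "exhausted"),
              sum(x$flags)))
  invisible(x)
}

#' Export an outlier report table as CSV
#' @param report an `outlier_report`.
#' @param path output file.
#' @export
write_outlier_report <- function(report, path) {
  tab <- report$table
  if (is.null(tab))
    tab <- data.frame(frame = integer(0), iteration = integer(0),
                      point = integer(0), md2 = numeric(0),
                      threshold = numeric(0), status = character(0))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
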
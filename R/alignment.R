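#' Rigid (or similarity) transform
#'
#' Maps a pose into another frame by `y = scale * x %*% rotation + translation`
#' (poses as `n_bp x d` matrices of row vectors). `rotation` is a proper
#' rotation (`det = +1`); `scale` is fixed at 1 under the rigid policy.
#'
#' @param rotation `d x d` proper orthogonal matrix.
#' @param translation length-`d` numeric vector.
#' @param scale positive scalar.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation, translation, scale = 1) {
  rotation <- as.matrix(rotation)
  d <- nrow(rotation)
  if (max(abs(crossprod(rotation) - diag(d))) > 1e-8)
    ssm_stop("rotation is not orthogonal", "ssmpose_model_error")
  if (det(rotation) < 0)
    ssm_stop("reflections are not allowed (det must be +1)", "ssmpose_model_error")
  if (scale <= 0) ssm_stop("scale must be positive", "ssmpose_model_error")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 scale = as.numeric(scale)), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> d = %d, scale = %.4g\n", nrow(x$rotation), x$scale))
  invisible(x)
}

#' Apply / invert a rigid transform
#'
#' `apply_transform` transforms every observed row of a pose matrix (rows that
#' are `NA` stay `NA`). `invert_transform` returns the inverse mapping, so
#' `apply_transform(apply_transform(x, t), invert_transform(t))` restores `x`.
#'
#' @param pose `n_bp x d` matrix (NA rows allowed).
#' @param transform a [rigid_transform()].
#' @export
apply_transform <- function(pose, transform) {
  out <- transform$scale * pose %*% transform$rotation
  sweep(out, 2L, transform$translation, `+`)
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  s <- 1 / transform$scale
  rigid_transform(Rt, -s * as.vector(transform$rotation %*% transform$translation), s)
}

#' Procrustes superimposition of one pose onto another
#'
#' Least-squares rigid (optionally similarity) alignment estimated on the
#' points observed in *both* poses via SVD of the cross-covariance of the
#' centred common points; reflections are excluded by forcing `det(R) = +1`.
#' The transform is applied to all observed source points; masked points stay
#' masked. The residual is the root-mean-square Euclidean point distance over
#' the common points after alignment.
#'
#' @param source,target `n_bp x d` pose matrices; missing points as `NA` rows.
#' @param policy `"rigid"` (default; scale fixed at 1) or `"similarity"`.
#' @param min_common minimum number of commonly observed points (default 3 in
#'   2D, 4 in 3D).
#' @return list with `aligned` (source in the target frame), `transform`
#'   (a [rigid_transform()]), `residual`, `n_common`.
#' @export
procrustes_align <- function(source, target, policy = c("rigid", "similarity"),
                             min_common = NULL) {
  policy <- match.arg(policy)
  d <- ncol(source)
  if (is.null(min_common)) min_common <- default_min_common(d)
  src_obs <- stats::complete.cases(source)
  tgt_obs <- stats::complete.cases(target)
  cube <- array(source, c(nrow(source), d, 1L))
  obs <- matrix(as.integer(src_obs), ncol = 1L)
  tgt <- target; tgt[!tgt_obs, ] <- 0      # masked ref rows excluded via ref_obs
  res <- cpp_align_batch(cube, obs, tgt, as.integer(tgt_obs), min_common,
                         policy == "similarity")
  if (res$ok[1] != 1L)
    ssm_stop(sprintf("alignment infeasible: %d common points (need >= %d)",
                     res$n_common[1], min_common), "ssmpose_alignment_error")
  list(aligned = matrix(res$aligned[, , 1], nrow(source), d),
       transform = rigid_transform(matrix(res$rotation[, , 1], d, d),
                                   res$translation[1, ], res$scale[1]),
       residual = res$residual[1], n_common = res$n_common[1])
}

# Align every frame of a dataset to a reference pose matrix. Returns aligned
# dataset plus per-frame transforms/residuals; frames with too few common
# points are flagged (ok = FALSE) and left NA in the aligned coords.
align_dataset <- function(dataset, ref, ref_obs = NULL, policy = "rigid",
                          min_common = NULL, frames = NULL) {
  d <- dataset$d
  if (is.null(min_common)) min_common <- default_min_common(d)
  if (is.null(ref_obs)) ref_obs <- stats::complete.cases(ref)
  ref0 <- ref; ref0[!ref_obs, ] <- 0
  idx <- if (is.null(frames)) seq_len(dataset$n_frames) else frames
  cube <- pose_cube(dataset)[, , idx, drop = FALSE]
  obs <- obs_matrix(dataset)[, idx, drop = FALSE]
  res <- cpp_align_batch(cube, obs, ref0, as.integer(ref_obs), min_common,
                         identical(policy, "similarity"))
  res$frames <- idx
  res
}

#' First quartile of pairwise aligned-pose distances
#'
#' Samples `n_pairs` random pose pairs, Procrustes-aligns each pair and
#' returns the 25th percentile of the RMS Euclidean distances. Used to
#' auto-tune the RANSAC neighbour threshold.
#'
#' @param dataset a [pose_dataset()].
#' @param n_pairs number of sampled pairs (default 2000; all distinct pairs
#'   are enumerated when fewer exist).
#' @param seed integer seed for pair sampling.
#' @param policy alignment policy.
#' @return scalar distance quantile.
#' @export
pairwise_distance_quartile <- function(dataset, n_pairs = 2000L, seed = 1L,
                                       policy = "rigid") {
  n <- dataset$n_frames
  if (n < 2L) ssm_stop("need at least two poses", "ssmpose_alignment_error")
  total <- n * (n - 1) / 2
  pairs <- with_seed(seed, {
    if (total <= n_pairs) {
      idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      cbind(idx[, 1], idx[, 2])
    } else {
      a <- sample.int(n, n_pairs, replace = TRUE)
      b <- sample.int(n - 1L, n_pairs, replace = TRUE)
      b <- b + (b >= a)
      cbind(a, b)
    }
  })
  cube <- pose_cube(dataset)
  obs <- obs_matrix(dataset)
  min_common <- default_min_common(dataset$d)
  dists <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    ref <- cube[, , b]
    ro <- obs[, b]
    ref[ro == 0L, ] <- 0
    r <- cpp_align_batch(cube[, , a, drop = FALSE], obs[, a, drop = FALSE],
                         ref, ro, min_common, identical(policy, "similarity"))
    if (r$ok[1] == 1L) dists[i] <- r$residual[1]
  }
  dists <- dists[is.finite(dists)]
  if (!length(dists))
    ssm_stop("no alignable pose pairs", "ssmpose_alignment_error")
  as.numeric(quantile(dists, 0.25, names = FALSE))
}
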
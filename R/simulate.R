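#' Contamination specification
#'
#' Parameters of the synthetic contamination process. A pose contains at
#' least one outlier with probability `p_op`; within such a pose each
#' landmark is independently displaced with probability `p_oep` (one landmark
#' forced so `p_op` is exact). Outlier displacements are additive
#' `N(0, sigma_o^2)` per coordinate, with `sigma_o` much larger than the
#' everywhere-present tracking noise `sigma_n`. Missing landmarks are
#' generated analogously with `p_mp` / `p_mep` and masked; a landmark that is
#' both displaced and missing ends up missing.
#'
#' @param sigma_n additive noise SD (default 0.1).
#' @param sigma_o outlier displacement SD (default `10 * sigma_n`).
#' @param p_op probability a pose contains at least one outlier.
#' @param p_oep per-landmark outlier probability within an outlier pose.
#' @param p_mp,p_mep same pair for missing landmarks.
#' @param seed integer seed driving the whole simulation.
#' @return object of class `contamination_spec`.
#' @export
contamination_spec <- function(sigma_n = 0.1, sigma_o = 10 * sigma_n,
                               p_op = 0, p_oep = 0.15, p_mp = 0, p_mep = 0.15,
                               seed = 1L) {
  ok <- sigma_n >= 0 && p_op >= 0 && p_op <= 1 && p_oep > 0 && p_oep <= 1 &&
    p_mp >= 0 && p_mp <= 1 && p_mep > 0 && p_mep <= 1
  if (!ok)
    ssm_stop("contamination probabilities must lie in [0, 1] (p_oep/p_mep in (0, 1]) and sigma_n >= 0",
             "ssmpose_config_error")
  if (p_op > 0 && sigma_o <= sigma_n)
    ssm_stop("outliers requested but sigma_o <= sigma_n", "ssmpose_config_error")
  structure(list(sigma_n = sigma_n, sigma_o = sigma_o, p_op = p_op,
                 p_oep = p_oep, p_mp = p_mp, p_mep = p_mep,
                 seed = as.integer(seed)),
            class = "contamination_spec")
}

#' Artificial mean shapes
#'
#' Fixture vertex sets of three artificial bodies with increasing vertex
#' counts — an irregular convex polygon ("poly", 10 vertices), a plus/cross
#' outline ("plus", 12 vertices) and an L outline ("L", 14 vertices) — or a
#' custom vertex list. Vertex counts are chosen so a pose retains enough
#' redundancy for outlier removal (a rank-5 shape model plus rigid motion has
#' ~11 degrees of freedom in 3D, so several landmarks must survive removal).
#' In 3D the outlines get a mild out-of-plane relief so rigid alignment is
#' never degenerate.
#'
#' @param name `"poly"`, `"plus"`, `"L"` or `"custom"`.
#' @param d 2 or 3.
#' @param vertices for `"custom"`: an `n_bp x d` coordinate matrix.
#' @return `n_bp x d` matrix of mean-pose vertices (centred).
#' @export
make_shape <- function(name = c("poly", "plus", "L", "custom"), d = 3L,
                       vertices = NULL) {
  name <- match.arg(name)
  if (name == "custom") {
    stopifnot(is.matrix(vertices), ncol(vertices) == d, nrow(vertices) >= 3L)
    v <- vertices
    if (qr(sweep(v, 2L, colMeans(v)))$rank < min(d, 2L) ||
        nrow(unique(v)) < 3L)
      warning("custom shape is degenerate (collinear/duplicated vertices); alignment may be unstable")
    return(v)
  }
  xy <- switch(name,
    poly = matrix(c( 2.0,  0.0,   1.7,  1.2,   0.6,  1.9,  -0.7,  1.8,
                    -1.7,  1.1,  -2.1,  0.0,  -1.6, -1.2,  -0.6, -2.0,
                     0.7, -1.9,   1.6, -1.1), ncol = 2, byrow = TRUE),
    plus = matrix(c( 0.6,  2.0,  -0.6,  2.0,  -0.6,  0.6,  -2.0,  0.6,
                    -2.0, -0.6,  -0.6, -0.6,  -0.6, -2.0,   0.6, -2.0,
                     0.6, -0.6,   2.0, -0.6,   2.0,  0.6,   0.6,  0.6),
                  ncol = 2, byrow = TRUE),
    L    = matrix(c(-1.0,  2.5,  -0.2,  2.5,  -0.2,  1.3,  -0.2,  0.1,
                    -0.2, -1.1,   0.8, -1.1,   1.8, -1.1,   1.8, -2.3,
                     0.8, -2.3,  -0.2, -2.3,  -1.0, -2.3,  -1.0, -1.1,
                    -1.0,  0.1,  -1.0,  1.3), ncol = 2, byrow = TRUE))
  if (d == 2L) v <- xy
  else {
    z <- 0.4 * sin(seq_len(nrow(xy)))          # deterministic mild relief
    v <- cbind(xy, z)
  }
  sweep(v, 2L, colMeans(v))
}

# Orthonormal basis of the rigid-motion tangent space at shape M (centred):
# d translation directions and d(d-1)/2 infinitesimal rotations vec(M G).
rigid_tangent_basis <- function(shape) {
  d <- ncol(shape); n_bp <- nrow(shape)
  Mc <- sweep(shape, 2L, colMeans(shape))
  cols <- list()
  for (a in seq_len(d)) {                      # translations
    e <- matrix(0, n_bp, d); e[, a] <- 1
    cols[[length(cols) + 1L]] <- vec_pose(e)
  }
  gens <- if (d == 3L) list(rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 0)),
                            rbind(c(0, 0, -1), c(0, 0, 0), c(1, 0, 0)),
                            rbind(c(0, 0, 0), c(0, 0, -1), c(0, 1, 0)))
          else list(rbind(c(0, -1), c(1, 0)))
  for (G in gens) cols[[length(cols) + 1L]] <- vec_pose(Mc %*% G)
  B <- do.call(cbind, cols)
  qr.Q(qr(B))[, seq_len(qr(B)$rank), drop = FALSE]
}

#' Random orthonormal eigenposes
#'
#' Draws standard-normal vectors and orthonormalizes them by Gram-Schmidt
#' (QR). By default the rigid-motion tangent directions at the mean shape
#' (translations and infinitesimal rotations) are projected out first:
#' deformation components lying in that subspace are absorbed by the
#' per-pose Procrustes alignment and are unrecoverable in principle, so
#' leaving them in would make the ground truth unidentifiable.
#'
#' @param shape `n_bp x d` mean shape (needed when `remove_rigid = TRUE`).
#' @param n_ep number of eigenposes.
#' @param seed integer seed.
#' @param remove_rigid project out rigid-motion directions (default TRUE).
#' @param d,n_bp alternative to `shape` when `remove_rigid = FALSE`.
#' @return `d*n_bp x n_ep` matrix with orthonormal columns.
#' @export
make_eigenposes <- function(shape = NULL, n_ep = 5L, seed = 1L,
                            remove_rigid = TRUE, d = NULL, n_bp = NULL) {
  if (!is.null(shape)) { d <- ncol(shape); n_bp <- nrow(shape) }
  stopifnot(!is.null(d), !is.null(n_bp))
  p <- d * n_bp
  if (n_ep > p) ssm_stop("n_ep cannot exceed d * n_bp", "ssmpose_config_error")
  W <- with_seed(seed, matrix(rnorm(p * n_ep), p, n_ep))
  if (remove_rigid) {
    if (is.null(shape))
      ssm_stop("remove_rigid = TRUE needs the mean shape", "ssmpose_config_error")
    B <- rigid_tangent_basis(shape)
    if (n_ep > p - ncol(B))
      ssm_stop("n_ep too large after removing rigid directions",
               "ssmpose_config_error")
    W <- W - B %*% crossprod(B, W)
  }
  Q <- qr.Q(qr(W))
  # fix signs so the result is deterministic across BLAS implementations
  sgn <- sign(Q[cbind(apply(abs(Q), 2L, which.max), seq_len(n_ep))])
  Q <- sweep(Q, 2L, sgn, `*`)
  Q[, seq_len(n_ep), drop = FALSE]
}

random_rotation <- function(d) {
  if (d == 2L) {
    th <- runif(1, 0, 2 * pi)
    matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  } else {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))     # uniform unit quaternion
    quat_to_rot(q)
  }
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# sample within-pose contaminated landmark set: each point Bernoulli(p),
# with at least one forced (uniform pick) so the pose-level rate is exact
sample_within <- function(n_bp, p) {
  hit <- runif(n_bp) < p
  if (!any(hit)) hit[sample.int(n_bp, 1L)] <- TRUE
  hit
}

#' Simulate a contaminated pose dataset with ground truth
#'
#' Generates `n_poses` poses as `(M + sum_j P_j b_j) R + T + E`: the mean
#' shape deformed along the eigenposes with per-pose Gaussian shape
#' parameters, independently rotated (uniform over SO(d)) and translated,
#' plus isotropic Gaussian noise. Outlier and missing contamination are then
#' planted per the [contamination_spec()] and all ground truth (clean poses
#' in both frames, transforms, shape parameters, masks) is recorded.
#'
#' @param shape `n_bp x d` mean shape (see [make_shape()]).
#' @param eigenposes orthonormal `d*n_bp x n_ep` matrix
#'   (see [make_eigenposes()]).
#' @param n_poses number of frames.
#' @param b_scales per-eigenpose SDs of the shape parameters (default
#'   geometric decay `0.8^(j-1)`).
#' @param spec a [contamination_spec()].
#' @param translation_scale SD of the random per-pose translation (default 5).
#' @return list with `dataset` (contaminated [pose_dataset()]) and `truth`
#'   (clean/noisy poses, aligned clean poses, mean shape, eigenposes, `b`,
#'   transforms, outlier and missing masks, the spec).
#' @export
simulate_dataset <- function(shape, eigenposes, n_poses,
                             b_scales = NULL, spec = contamination_spec(),
                             translation_scale = 5) {
  d <- ncol(shape); n_bp <- nrow(shape); p <- d * n_bp
  n_ep <- ncol(eigenposes)
  if (is.null(b_scales)) b_scales <- 0.8^(seq_len(n_ep) - 1)
  if (length(b_scales) != n_ep)
    ssm_stop("length(b_scales) must equal the number of eigenposes",
             "ssmpose_config_error")
  with_seed(spec$seed, {
    b <- matrix(rnorm(n_poses * n_ep), n_poses, n_ep) %*% diag(b_scales, n_ep)
    defo <- b %*% t(eigenposes)                       # n x p deviations
    clean_aligned <- array(0, c(n_poses, n_bp, d))
    clean <- array(0, c(n_poses, n_bp, d))
    rots <- array(0, c(d, d, n_poses))
    trans <- matrix(rnorm(n_poses * d, sd = translation_scale), n_poses, d)
    for (i in seq_len(n_poses)) {
      Pi <- shape + unvec_pose(defo[i, ], d)
      clean_aligned[i, , ] <- Pi
      R <- random_rotation(d)
      rots[, , i] <- R
      clean[i, , ] <- sweep(Pi %*% R, 2L, trans[i, ], `+`)
    }
    noisy <- clean + array(rnorm(length(clean), sd = spec$sigma_n), dim(clean))
    out_mask <- matrix(FALSE, n_poses, n_bp)
    if (spec$p_op > 0) {
      op <- runif(n_poses) < spec$p_op
      for (i in which(op)) out_mask[i, ] <- sample_within(n_bp, spec$p_oep)
    }
    miss_mask <- matrix(FALSE, n_poses, n_bp)
    if (spec$p_mp > 0) {
      mp <- runif(n_poses) < spec$p_mp
      for (i in which(mp)) miss_mask[i, ] <- sample_within(n_bp, spec$p_mep)
    }
    contaminated <- noisy
    n_out <- sum(out_mask)
    if (n_out) {
      disp <- matrix(rnorm(n_out * d, sd = spec$sigma_o), n_out, d)
      for (k in seq_len(d)) {
        slab <- contaminated[, , k]
        slab[out_mask] <- slab[out_mask] + disp[, k]
        contaminated[, , k] <- slab
      }
    }
    dataset <- pose_dataset(contaminated, mask = miss_mask)
    truth <- list(clean = clean, noisy = noisy, clean_aligned = clean_aligned,
                  mean_shape = shape, eigenposes = eigenposes, b = b,
                  rotations = rots, translations = trans,
                  outlier_mask = out_mask, missing_mask = miss_mask,
                  spec = spec)
    list(dataset = dataset, truth = truth)
  })
}

#' Contamination grid
#'
#' Cross-product of contamination levels used to regenerate robustness
#' curves. Defaults: within-pose outlier fractions {0.05, 0.15, 0.25},
#' pose-level outlier probabilities 0.05...0.5.
#'
#' @param base a [contamination_spec()] providing noise scales.
#' @param p_op,p_oep,p_mp,p_mep level vectors (scalars allowed).
#' @param n_reps replicates per cell.
#' @param seeds optional integer matrix/vector of seeds; by default derived
#'   deterministically from `base$seed`.
#' @return data frame with one row per (cell, rep): contamination levels,
#'   `rep`, `seed`. Pass each row to [grid_spec()] to obtain the cell's
#'   [contamination_spec()].
#' @export
contamination_grid <- function(base = contamination_spec(),
                               p_op = seq(0.05, 0.5, length.out = 6),
                               p_oep = c(0.05, 0.15, 0.25),
                               p_mp = 0, p_mep = 0.15,
                               n_reps = 1L, seeds = NULL) {
  g <- expand.grid(p_op = p_op, p_oep = p_oep, p_mp = p_mp, p_mep = p_mep,
                   rep = seq_len(n_reps), KEEP.OUT.ATTRS = FALSE)
  g$seed <- if (is.null(seeds))
    (base$seed + 7919L * seq_len(nrow(g))) %% .Machine$integer.max
  else rep_len(as.integer(seeds), nrow(g))
  g$sigma_n <- base$sigma_n
  g$sigma_o <- base$sigma_o
  g
}

#' @rdname contamination_grid
#' @param row one row of the grid data frame.
#' @export
grid_spec <- function(row) {
  contamination_spec(sigma_n = row$sigma_n, sigma_o = row$sigma_o,
                     p_op = row$p_op, p_oep = row$p_oep,
                     p_mp = row$p_mp, p_mep = row$p_mep, seed = row$seed)
}
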
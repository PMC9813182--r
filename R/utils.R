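#' @useDynLib ssmpose, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats mad median qchisq pchisq rnorm runif rbinom cor quantile sd
#' @importFrom utils read.csv write.csv modifyList
NULL

# Classed errors so callers can distinguish data/format problems from bugs.
ssm_stop <- function(msg, class) {
  stop(structure(class = c(class, "ssmpose_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Evaluate expr with the global RNG seeded at `seed`, restoring the previous
# RNG state afterwards so library calls never disturb user-level randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# point-major vectorisation: (x1, y1[, z1], x2, y2, ...)
vec_pose <- function(pose) as.vector(t(pose))

unvec_pose <- function(x, d) matrix(x, ncol = d, byrow = TRUE)

# coordinate indices of a set of point indices in the vectorised pose
coord_idx <- function(points, d) {
  as.vector(t(outer((points - 1L) * d, seq_len(d), `+`)))
}

# n_bp x d x n cube view used by the C++ kernels
pose_cube <- function(dataset) aperm(dataset$coords, c(2L, 3L, 1L))

cube_to_coords <- function(cube) aperm(cube, c(3L, 1L, 2L))

obs_matrix <- function(dataset) {
  m <- t(!dataset$mask)
  storage.mode(m) <- "integer"
  m
}

# 3 non-collinear points determine a rigid transform in both 2D and 3D; a
# larger value is safer but eats into greedy-removal headroom on small bodies
default_min_common <- function(d) 3L
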
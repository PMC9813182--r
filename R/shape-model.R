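#' Statistical shape model
#'
#' A multivariate Gaussian over aligned, vectorised poses: mean pose `mu`,
#' `r` orthonormal eigenposes (columns of `eigenposes`), their eigenvalues and
#' an isotropic noise floor `sigma2` on the remaining directions. The
#' regularized covariance is
#' `C = sigma2 * I + V diag(eigenvalues - sigma2) V'`, which is full-rank SPD
#' whenever every eigenvalue >= `sigma2 > 0`.
#'
#' Vectorisation is point-major: point `i` occupies coordinates
#' `(i-1)*d + 1 ... i*d`.
#'
#' @param mu numeric mean pose vector, length `d * n_bp`.
#' @param eigenposes `d*n_bp x r` matrix with orthonormal columns.
#' @param eigenvalues nonincreasing positive vector, length `r`.
#' @param sigma2 positive noise floor, `<= min(eigenvalues)`.
#' @param d spatial dimensionality (2 or 3).
#' @param alignment_policy `"rigid"` or `"similarity"` (how poses were brought
#'   into the model frame).
#' @param point_names optional landmark names.
#' @return object of class `shape_model`.
#' @export
shape_model <- function(mu, eigenposes, eigenvalues, sigma2, d,
                        alignment_policy = c("rigid", "similarity"),
                        point_names = NULL) {
  alignment_policy <- match.arg(alignment_policy)
  eigenposes <- as.matrix(eigenposes)
  p <- length(mu); r <- ncol(eigenposes)
  if (nrow(eigenposes) != p || length(eigenvalues) != r)
    ssm_stop("inconsistent shape-model dimensions", "ssmpose_model_error")
  if (p %% d != 0L)
    ssm_stop("length(mu) must be a multiple of d", "ssmpose_model_error")
  gram <- crossprod(eigenposes)
  if (max(abs(gram - diag(r))) > 1e-8)
    ssm_stop("eigenposes are not orthonormal", "ssmpose_model_error")
  if (is.unsorted(rev(eigenvalues)))
    ssm_stop("eigenvalues must be nonincreasing", "ssmpose_model_error")
  if (sigma2 <= 0 || any(eigenvalues < sigma2 - 1e-12))
    ssm_stop("need 0 < sigma2 <= min(eigenvalues)", "ssmpose_model_error")
  structure(list(mu = as.numeric(mu), eigenposes = eigenposes,
                 eigenvalues = as.numeric(eigenvalues),
                 sigma2 = as.numeric(sigma2), d = as.integer(d),
                 n_bp = as.integer(p / d), r = as.integer(r),
                 alignment_policy = alignment_policy,
                 point_names = point_names),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model> %d points, d = %d, r = %d eigenposes\n",
              x$n_bp, x$d, x$r))
  cat("  eigenvalues:", signif(x$eigenvalues, 4), "\n")
  cat(sprintf("  noise floor sigma2 = %.4g, alignment = %s\n",
              x$sigma2, x$alignment_policy))
  invisible(x)
}

#' Regularized model covariance
#'
#' Dense `d*n_bp` square covariance implied by the shape model:
#' top-`r` eigenpairs plus the isotropic `sigma2` floor.
#'
#' @param model a [shape_model()].
#' @return symmetric positive-definite matrix.
#' @export
model_covariance <- function(model) {
  p <- length(model$mu)
  V <- model$eigenposes
  C <- diag(model$sigma2, p) + V %*% (t(V) * (model$eigenvalues - model$sigma2))
  (C + t(C)) / 2
}

#' Mean pose as a landmark matrix
#' @param model a [shape_model()].
#' @return `n_bp x d` matrix.
#' @export
mean_pose_matrix <- function(model) unvec_pose(model$mu, model$d)
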
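# Independent oracles used by the dual-route checks. These deliberately use
# different algorithms (numerical optimization, dense inverses, brute-force
# enumeration) from the implementation paths they validate.

quat_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# Brute-force rigid Procrustes in 3D: optimize a quaternion with many
# restarts, translation solved by centroid matching.
oracle_procrustes_3d <- function(src, tgt, n_starts = 20) {
  cs <- colMeans(src); ct <- colMeans(tgt)
  S <- sweep(src, 2, cs); T <- sweep(tgt, 2, ct)
  obj <- function(q) {
    R <- quat_rotation(q)
    sum((S %*% R - T)^2)
  }
  best <- Inf; best_R <- diag(3)
  starts <- rbind(c(1, 0, 0, 0),
                  matrix(rnorm(4 * (n_starts - 1)), n_starts - 1, 4))
  for (i in seq_len(nrow(starts))) {
    op <- optim(starts[i, ], obj, method = "BFGS",
                control = list(maxit = 500, reltol = 1e-15))
    if (op$value < best) { best <- op$value; best_R <- quat_rotation(op$par) }
  }
  list(residual = sqrt(best / nrow(src)), rotation = best_R,
       translation = ct - as.vector(cs %*% best_R))
}

# Dense-inverse Mahalanobis oracle.
oracle_md2 <- function(x, mu, C) as.numeric(t(x - mu) %*% solve(C) %*% (x - mu))

# Numerical maximizer of the joint Gaussian log-density over the missing
# block (equivalent to maximizing the conditional density).
oracle_conditional <- function(x_in, mu, C, idx_m, idx_in) {
  Cinv <- solve(C)
  obj <- function(xm) {
    full <- numeric(length(mu))
    full[idx_m] <- xm; full[idx_in] <- x_in
    dev <- full - mu
    0.5 * as.numeric(t(dev) %*% Cinv %*% dev)
  }
  op <- optim(mu[idx_m], obj, method = "BFGS",
              control = list(maxit = 1000, reltol = 1e-15))
  op$par
}

random_spd <- function(p) {
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + diag(0.5, p)
}

random_rotation_3d <- function() quat_rotation(rnorm(4))

rotation_2d <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)

# Small simulated dataset bundle shared across tests.
sim_bundle <- function(n = 400, d = 3, n_ep = 5, spec = contamination_spec(seed = 5),
                       shape_name = "poly", eigen_seed = 2) {
  shape <- make_shape(shape_name, d = d)
  P <- make_eigenposes(shape, n_ep = n_ep, seed = eigen_seed)
  sim <- simulate_dataset(shape, P, n, spec = spec)
  sim$shape <- shape
  sim$P <- P
  sim
}

unvec_mu <- function(mu, d = 3) matrix(mu, ncol = d, byrow = TRUE)

vec_pose_t <- function(pose) as.vector(t(pose))

rms_diff <- function(a, b) sqrt(mean((a - b)^2))

# A tiny true model with known parameters (no fitting involved).
toy_model <- function(d = 3, seed = 3, n_ep = 5, sigma2 = 0.01,
                      b_scales = 0.8^(seq_len(n_ep) - 1)) {
  shape <- make_shape("poly", d = d)
  P <- make_eigenposes(shape, n_ep = n_ep, seed = seed)
  shape_model(as.vector(t(shape)), P, b_scales^2 + sigma2, sigma2, d)
}
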
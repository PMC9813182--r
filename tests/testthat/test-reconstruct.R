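test_that("conditional imputation satisfies the closed-form identities", {
  m <- toy_model(seed = 6)
  mu_mat <- mean_pose_matrix(m)
  # x_in = mu_in -> x_m = mu_m
  pose <- mu_mat
  pose[c(2, 7), ] <- NA
  expect_equal(conditional_impute(pose, m), mu_mat, tolerance = 1e-12)
  # diagonal covariance -> x_m = mu_m regardless of inliers
  p <- 12
  dm <- shape_model(rnorm(p), diag(p)[, 1:3], c(3, 2, 1.5), 1, 3)
  # force a diagonal covariance: eigenposes along coordinate axes
  dpose <- mean_pose_matrix(dm) + matrix(rnorm(p, sd = 2), 4, 3)
  dpose[2, ] <- NA
  out <- conditional_impute(dpose, dm)
  # coordinates of point 2 sit outside the first three axes -> pure mu
  expect_equal(out[2, ], mean_pose_matrix(dm)[2, ], tolerance = 1e-10)
  expect_error(conditional_impute(matrix(NA_real_, m$n_bp, 3), m),
               class = "ssmpose_data_error")
})

test_that("conditional imputation matches the numerical maximizer of the joint density", {
  set.seed(30)
  m <- toy_model(seed = 6)
  C <- model_covariance(m)
  for (rep in 1:10) {
    pose <- mean_pose_matrix(m) + unvec_mu(as.vector(chol(C) %*% rnorm(30)))
    miss <- sort(sample(10, sample(1:3, 1)))
    pose_m <- pose; pose_m[miss, ] <- NA
    imp <- conditional_impute(pose_m, m)
    ci_m <- sort(as.vector(outer(1:3, (miss - 1) * 3, `+`)))
    ci_in <- setdiff(seq_len(30), ci_m)
    oracle <- oracle_conditional(vec_pose_t(pose)[ci_in], m$mu, C, ci_m, ci_in)
    expect_equal(vec_pose_t(imp)[ci_m], oracle, tolerance = 1e-6)
  }
})

test_that("imputation is exact in the zero-noise sufficient-inlier limit", {
  set.seed(31)
  shape <- make_shape("poly", d = 3)
  P <- make_eigenposes(shape, n_ep = 3, seed = 7)
  m <- shape_model(vec_pose_t(shape), P, c(1, 0.8, 0.6), 1e-12, 3)
  for (rep in 1:5) {
    b <- rnorm(3) * sqrt(c(1, 0.8, 0.6))
    truth <- shape + unvec_mu(as.vector(P %*% b))
    pose <- truth
    miss <- sample(10, 2)
    pose[miss, ] <- NA
    imp <- conditional_impute(pose, m)
    expect_equal(imp[miss, ], truth[miss, ], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("shape parameters satisfy the projection identities", {
  m <- toy_model(seed = 6)
  expect_equal(shape_parameters(m$mu, m), rep(0, 5))
  x <- m$mu + 2 * m$eigenposes[, 1]
  expect_equal(shape_parameters(x, m), c(2, rep(0, 4)), tolerance = 1e-10)
  # round trip reproduces the rank-r component
  set.seed(32)
  x2 <- m$mu + as.vector(m$eigenposes %*% rnorm(5))
  b <- shape_parameters(x2, m)
  expect_equal(m$mu + as.vector(m$eigenposes %*% b), x2, tolerance = 1e-10)
})

test_that("reconstruction is a no-op on complete clean data and never alters inliers", {
  set.seed(33)
  m <- toy_model(seed = 6)
  shape <- mean_pose_matrix(m)
  n <- 20
  coords <- array(NA_real_, c(n, 10, 3))
  for (i in 1:n) {
    pose <- shape + unvec_mu(as.vector(m$eigenposes %*%
      (rnorm(5) * sqrt(m$eigenvalues - m$sigma2))))
    coords[i, , ] <- sweep(pose %*% random_rotation_3d(), 2, rnorm(3), `+`)
  }
  ds <- pose_dataset(coords)
  rec <- reconstruct_dataset(ds, m)
  expect_identical(rec$recovered$coords, ds$coords)   # bit-for-bit
  # with some masked points, observed entries still pass through untouched
  coords2 <- coords
  coords2[3, 5, ] <- NA
  ds2 <- pose_dataset(coords2)
  rec2 <- reconstruct_dataset(ds2, m)
  keep <- !is.na(coords2)
  expect_identical(rec2$recovered$coords[keep], coords2[keep])
  expect_identical(sum(rec2$recovered$mask), 0L)      # gap was filled
  expect_lt(rms_diff(rec2$recovered$coords[3, 5, ], coords[3, 5, ]), 0.5)
})

test_that("model imputation beats mean substitution by a wide margin", {
  spec <- contamination_spec(p_mp = 0.25, p_mep = 0.15, seed = 40)
  sim <- sim_bundle(n = 300, spec = spec)
  fit <- fit_ssm(sim$dataset, fit_config(seed = 2, n_ransac_iter = 30))
  rec <- reconstruct_dataset(sim$dataset, fit$model)
  mm <- sim$truth$missing_mask
  err_model <- rmse(rec$recovered$coords, sim$truth$clean, "masked_only", mm)
  # mu-substitution baseline on the same masks: place the model mean point
  # after aligning the mean pose to each frame's observed points
  base <- sim$dataset$coords
  mu_mat <- mean_pose_matrix(fit$model)
  for (i in which(rowSums(mm) > 0)) {
    obs_pts <- which(!sim$dataset$mask[i, ])
    pose <- matrix(sim$dataset$coords[i, , ], 10, 3)
    al <- procrustes_align(mu_mat[obs_pts, , drop = FALSE], pose[obs_pts, , drop = FALSE])
    placed <- apply_transform(mu_mat, al$transform)
    base[i, mm[i, ], ] <- placed[mm[i, ], ]
  }
  err_mean <- rmse(base, sim$truth$clean, "masked_only", mm)
  expect_lt(err_model, err_mean / 3)
})

test_that("run pipeline is deterministic and dimension-generic", {
  spec <- contamination_spec(p_op = 0.15, p_oep = 0.15, sigma_o = 1, seed = 41)
  sim3 <- sim_bundle(n = 200, d = 3, spec = spec)
  cfg <- fit_config(seed = 9, n_ransac_iter = 20)
  r1 <- recover_poses(sim3$dataset, cfg)
  r2 <- recover_poses(sim3$dataset, cfg)
  expect_identical(r1$recovered$coords, r2$recovered$coords)
  expect_identical(r1$fit$model, r2$fit$model)

  # d = 2 runs through the identical code path
  sim2 <- sim_bundle(n = 200, d = 2, spec = contamination_spec(
    p_op = 0.15, p_oep = 0.15, sigma_o = 1, p_mp = 0.1, p_mep = 0.15, seed = 42))
  r2d <- recover_poses(sim2$dataset, cfg)
  expect_identical(r2d$recovered$d, 2L)
  expect_identical(sum(r2d$recovered$mask[setdiff(1:200, r2d$skipped), ]), 0L)
  expect_lt(rmse(r2d$recovered$coords, sim2$truth$clean),
            rmse(sim2$dataset$coords, sim2$truth$clean))
})
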
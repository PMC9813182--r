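test_that("RANSAC reference selection prefers inlier poses", {
  # 50-pose fixture: one true shape under rigid motions + 30% wild poses.
  set.seed(10)
  shape <- make_shape("poly", d = 3)
  coords <- array(NA_real_, c(50, 10, 3))
  for (i in 1:50) {
    base <- if (i <= 35) shape else matrix(rnorm(30, sd = 3), 10, 3)
    coords[i, , ] <- sweep((base + matrix(rnorm(30, sd = 0.05), 10, 3)) %*%
                             random_rotation_3d(), 2, rnorm(3), `+`)
  }
  ds <- pose_dataset(coords)
  sel <- select_reference_pose(ds, fit_config(seed = 1))
  expect_lte(sel$reference, 35L)          # an inlier pose wins
  expect_gt(sel$score, 10)

  # exhaustive check: score of the winner >= exhaustive score of any outlier
  # candidate under the same threshold, scoring the full dataset
  score_all <- function(cand) {
    ref <- matrix(coords[cand, , ], 10, 3)
    s <- 0
    for (j in 1:50)
      s <- s + (procrustes_align(matrix(coords[j, , ], 10, 3), ref)$residual <
                  sel$threshold)
    s
  }
  expect_gte(score_all(sel$reference), max(sapply(36:50, score_all)))
})

test_that("identical poses give score = subsample size; zero threshold counts duplicates", {
  base <- make_shape("plus", d = 2)
  coords <- array(rep(base, each = 20), c(20, nrow(base), 2))
  ds <- pose_dataset(coords)
  cfg <- fit_config(seed = 2, n_ransac_iter = 5)
  sel <- select_reference_pose(ds, cfg, threshold = 0.5)
  expect_equal(sel$score, ceiling(0.5 * 20))
  # threshold 0 counts strictly-below-zero distances -> none
  sel0 <- select_reference_pose(ds, cfg, threshold = 0)
  expect_identical(sel0$score, 0L)
})

test_that("mean pose is recovered from rigid motions; robust to a contaminating shape", {
  set.seed(11)
  shape <- make_shape("poly", d = 3)
  coords <- array(NA_real_, c(60, 10, 3))
  for (i in 1:60)
    coords[i, , ] <- sweep(shape %*% random_rotation_3d(), 2, rnorm(3), `+`)
  est <- estimate_mean_pose(pose_dataset(coords), fit_config(seed = 1))
  al <- procrustes_align(unvec_mu(est$mu), shape)
  expect_lt(rms_diff(al$aligned, shape), 1e-8)

  # 25% of poses replaced by a distant second shape: the consensus mean
  # recovers the majority shape, not the mixture mean
  far <- shape + matrix(rnorm(30, sd = 5), 10, 3)
  for (i in 46:60)
    coords[i, , ] <- sweep(far %*% random_rotation_3d(), 2, rnorm(3), `+`)
  ds <- pose_dataset(coords)
  est2 <- estimate_mean_pose(ds, fit_config(seed = 1))
  # oracle: mask-aware mean over labelled inliers aligned to the same reference
  al2 <- procrustes_align(unvec_mu(est2$mu), shape)
  expect_lt(rms_diff(al2$aligned, shape), 0.05 * sqrt(mean(shape^2)))
})

test_that("mean pose error shrinks roughly as 1/sqrt(n) with additive noise", {
  shape <- make_shape("poly", d = 3)
  errs <- sapply(c(50, 200, 800), function(n) {
    mean(sapply(1:3, function(rep) {
      set.seed(100 * rep + n)
      coords <- array(NA_real_, c(n, 10, 3))
      for (i in seq_len(n))
        coords[i, , ] <- sweep((shape + matrix(rnorm(30, sd = 0.2), 10, 3)) %*%
                                 random_rotation_3d(), 2, rnorm(3), `+`)
      est <- estimate_mean_pose(pose_dataset(coords),
                                fit_config(seed = rep, n_ransac_iter = 20))
      rms_diff(procrustes_align(unvec_mu(est$mu), shape)$aligned, shape)
    }))
  })
  # log-log slope vs n should be near -1/2
  slope <- coef(lm(log(errs) ~ log(c(50, 200, 800))))[2]
  expect_lt(slope, -0.3)
  expect_gt(slope, -0.7)
})

test_that("knn imputation matches hand-enumerated neighbour averages", {
  # identical poses: imputed value equals the common value exactly
  base <- make_shape("poly", d = 2)
  coords <- array(rep(base, each = 10), c(10, 10, 2))
  coords[3, 5, ] <- NA
  imp <- knn_impute(pose_dataset(coords), k = 4)
  expect_equal(imp$coords[3, 5, ], base[5, ], tolerance = 1e-10)
  expect_identical(sum(imp$mask), 0L)

  # k = n - 1 on an already-aligned dataset equals the mask-aware mean
  set.seed(12)
  coords2 <- array(rep(base, each = 10), c(10, 10, 2)) +
    array(rnorm(200, sd = 1e-3), c(10, 10, 2))   # tiny noise: alignment ~ identity
  coords2[1, 2, ] <- NA
  ds2 <- pose_dataset(coords2)
  imp2 <- knn_impute(ds2, k = 9)
  expect_equal(imp2$coords[1, 2, ], colMeans(coords2[2:10, 2, ]),
               tolerance = 2e-3)

  # k = 3: brute-force ranking by aligned distance over observed points
  set.seed(13)
  coords3 <- array(rnorm(10 * 10 * 3, sd = 1), c(10, 10, 3))
  for (i in 1:10) coords3[i, , ] <- coords3[i, , ] + 3 * make_shape("poly", d = 3)
  coords3[4, 7, ] <- NA
  ds3 <- pose_dataset(coords3)
  imp3 <- knn_impute(ds3, k = 3)
  tgt <- matrix(coords3[4, , ], 10, 3)
  cand <- setdiff(1:10, 4)
  dists <- sapply(cand, function(j)
    procrustes_align(matrix(coords3[j, , ], 10, 3)[-7, ], tgt[-7, ])$residual)
  near <- cand[order(dists)][1:3]
  vals <- sapply(near, function(j) {
    al <- procrustes_align(matrix(coords3[j, , ], 10, 3)[-7, ], tgt[-7, ])
    apply_transform(matrix(coords3[j, , ], 10, 3), al$transform)[7, ]
  })
  expect_equal(imp3$coords[4, 7, ], rowMeans(vals), tolerance = 1e-8)

  # a missing position with zero recovering poses -> error naming the point
  coords4 <- coords3
  coords4[, 7, ] <- NA
  expect_error(knn_impute(pose_dataset(coords4), k = 3),
               class = "ssmpose_data_error")
})

test_that("OGK covariance is accurate on clean data and robust under contamination", {
  set.seed(14)
  p <- 6; n <- 10000
  S0 <- random_spd(p)
  L <- chol(S0)
  X <- matrix(rnorm(n * p), n, p) %*% L
  C <- ogk_covariance(X)
  rel <- function(A, B) norm(A - B, "F") / norm(B, "F")
  expect_lt(rel(C, S0), 0.1)
  expect_lt(rel(C, cov(X)), 0.05)

  # 20% of rows at 50 sigma: OGK barely moves, sample covariance explodes
  Xc <- X
  idx <- sample(n, n / 5)
  Xc[idx, ] <- Xc[idx, ] + matrix(rnorm(length(idx) * p, sd = 50), length(idx), p)
  expect_lt(rel(ogk_covariance(Xc), S0), 0.15)
  expect_gt(rel(cov(Xc), S0), 10)

  # univariate reduction: p = 1 equals the squared robust scale
  x <- rnorm(500, sd = 2.5)
  expect_equal(as.numeric(ogk_covariance(matrix(x), reweight = FALSE)),
               mad(x)^2, tolerance = 1e-12)
  # determinism
  expect_identical(ogk_covariance(X[1:500, ]), ogk_covariance(X[1:500, ]))
})

test_that("ppca regularization identities hold exactly", {
  # identity covariance
  reg <- ppca_regularize(diag(6), r_or_frac = 2)
  expect_equal(reg$sigma2, 1)
  V <- reg$eigenposes
  Ctilde <- reg$sigma2 * diag(6) + V %*% (t(V) * (reg$eigenvalues - reg$sigma2))
  expect_equal(Ctilde, diag(6), tolerance = 1e-12)

  # the printed arithmetic: diag(5,4,1,1,1,1), r = 2 -> sigma2 = 1
  reg2 <- ppca_regularize(diag(c(5, 4, 1, 1, 1, 1)), r_or_frac = 2)
  expect_equal(reg2$sigma2, 1, tolerance = 1e-12)
  expect_equal(reg2$eigenvalues, c(5, 4), tolerance = 1e-12)

  # trace conservation on random SPD for several ranks
  set.seed(15)
  C <- random_spd(8)
  for (r in c(1, 3, 5)) {
    reg3 <- ppca_regularize(C, r_or_frac = r)
    expect_equal(sum(reg3$eigenvalues) + (8 - r) * reg3$sigma2, sum(diag(C)),
                 tolerance = 1e-10)
  }
  # variance_fraction policy picks the smallest rank reaching the target
  regv <- ppca_regularize(diag(c(8, 1, 1, 0, 0, 0)), "variance_fraction", 0.8)
  expect_identical(regv$r, 1L)
  expect_error(ppca_regularize(diag(3), r_or_frac = 3),
               class = "ssmpose_model_error")
})

test_that("fitted models satisfy invariants, are deterministic and equivariant", {
  sim <- sim_bundle(n = 250, spec = contamination_spec(p_op = 0.1, p_oep = 0.15,
                                                       sigma_o = 1, seed = 21))
  cfg <- fit_config(seed = 5, n_ransac_iter = 30)
  fit1 <- fit_ssm(sim$dataset, cfg)
  fit2 <- fit_ssm(sim$dataset, cfg)
  expect_identical(fit1$model, fit2$model)          # bit-identical per seed

  # SPD: Cholesky succeeds; orthonormal eigenposes; eigenvalues >= sigma2
  expect_no_error(chol(model_covariance(fit1$model)))
  expect_lt(max(abs(crossprod(fit1$model$eigenposes) - diag(fit1$model$r))), 1e-10)
  expect_true(all(fit1$model$eigenvalues >= fit1$model$sigma2 - 1e-12))

  # equivariance: one global rigid motion leaves eigenvalues, sigma2 and
  # eigenpose similarities unchanged up to the (documented) non-equivariance
  # of the OGK pairwise scales, a few percent
  R <- random_rotation_3d()
  coords <- sim$dataset$coords
  for (i in seq_len(dim(coords)[1]))
    coords[i, , ] <- sweep(matrix(coords[i, , ], 10, 3) %*% R, 2, c(3, -1, 2), `+`)
  fitR <- fit_ssm(pose_dataset(coords, mask = sim$dataset$mask), cfg)
  expect_equal(fitR$model$eigenvalues, fit1$model$eigenvalues, tolerance = 0.05)
  expect_equal(fitR$model$sigma2, fit1$model$sigma2, tolerance = 0.05)
  sp <- eigenpose_similarity(fit1$model$eigenposes, fitR$model$eigenposes,
                             mean_true = mean_pose_matrix(fit1$model),
                             mean_est = mean_pose_matrix(fitR$model))
  expect_true(all(sp > 0.98))
})

test_that("eigenvalue estimates tighten with sample size on clean simulations", {
  shape <- make_shape("poly", d = 3)
  P <- make_eigenposes(shape, n_ep = 5, seed = 2)
  true_ev <- (0.8^(0:4))^2 + 0.01
  err <- sapply(c(500, 2000), function(n) {
    sim <- simulate_dataset(shape, P, n, spec = contamination_spec(seed = n))
    fit <- fit_ssm(sim$dataset, fit_config(seed = 1, n_ransac_iter = 20))
    mean(abs(fit$model$eigenvalues - true_ev) / true_ev)
  })
  expect_lt(err[2], err[1] + 0.02)   # non-increasing up to noise
  expect_lt(err[2], 0.15)
})
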
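test_that("procrustes recovers known rigid transforms exactly", {
  set.seed(1)
  for (d in c(2L, 3L)) {
    pose <- matrix(rnorm(6 * d), 6, d)
    R0 <- if (d == 3) random_rotation_3d() else rotation_2d(runif(1, 0, 2 * pi))
    t0 <- rnorm(d)
    moved <- sweep(pose %*% R0, 2, t0, `+`)

    # identity case
    al0 <- procrustes_align(pose, pose)
    expect_lt(al0$residual, 1e-12)
    expect_equal(al0$transform$rotation, diag(d), tolerance = 1e-10)

    # recover (R0, t0): aligning moved onto pose inverts the motion
    al <- procrustes_align(moved, pose)
    expect_lt(al$residual, 1e-10)
    expect_equal(al$transform$rotation, t(R0), tolerance = 1e-8)
    expect_equal(matrix(al$aligned, 6, d), pose, tolerance = 1e-8)
  }
})

test_that("masked points are excluded from the fit but stay masked", {
  set.seed(2)
  pose <- matrix(rnorm(18), 6, 3)
  R0 <- random_rotation_3d(); t0 <- rnorm(3)
  moved <- sweep(pose %*% R0, 2, t0, `+`)
  moved[c(2, 5), ] <- NA
  al <- procrustes_align(moved, pose)
  expect_lt(al$residual, 1e-10)
  expect_true(all(is.na(al$aligned[c(2, 5), ])))
  expect_equal(al$aligned[-c(2, 5), ], pose[-c(2, 5), ], tolerance = 1e-8)
  expect_identical(al$n_common, 4L)
  # too few common points -> classed error carrying the count
  moved2 <- moved; moved2[c(1, 3), ] <- NA
  err <- tryCatch(procrustes_align(moved2, pose), error = identity)
  expect_s3_class(err, "ssmpose_alignment_error")
  expect_match(conditionMessage(err), "2 common")
})

test_that("procrustes matches the brute-force quaternion optimizer", {
  set.seed(3)
  for (rep in 1:6) {
    n <- sample(4:6, 1)
    src <- matrix(rnorm(3 * n), n, 3)
    tgt <- matrix(rnorm(3 * n), n, 3)
    al <- procrustes_align(src, tgt, min_common = 3)
    bf <- oracle_procrustes_3d(src, tgt)
    expect_equal(al$residual, bf$residual, tolerance = 1e-6)
    expect_lte(al$residual, bf$residual + 1e-6)   # never worse than oracle
  }
})

test_that("alignment residual is invariant under rigid motions and scale under similarity", {
  set.seed(4)
  src <- matrix(rnorm(15), 5, 3)
  tgt <- matrix(rnorm(15), 5, 3)
  base <- procrustes_align(src, tgt)$residual
  for (rep in 1:5) {
    R <- random_rotation_3d(); tr <- rnorm(3)
    expect_equal(procrustes_align(sweep(src %*% R, 2, tr, `+`), tgt)$residual,
                 base, tolerance = 1e-8)
    expect_equal(procrustes_align(src, sweep(tgt %*% R, 2, tr, `+`))$residual,
                 base, tolerance = 1e-8)
  }
  sim_base <- procrustes_align(src, tgt, policy = "similarity")$residual
  expect_equal(procrustes_align(2.7 * src, tgt, policy = "similarity")$residual,
               sim_base, tolerance = 1e-8)
  # rigid residual is NOT scale-invariant
  expect_gt(procrustes_align(2.7 * src, tgt)$residual, base)
})

test_that("rotations are proper: reflections are never returned", {
  set.seed(5)
  for (rep in 1:20) {
    src <- matrix(rnorm(12), 4, 3)
    tgt <- matrix(rnorm(12), 4, 3)
    expect_gt(det(procrustes_align(src, tgt)$transform$rotation), 0)
  }
})

test_that("apply/invert transform compose to identity", {
  set.seed(6)
  pose <- matrix(rnorm(15), 5, 3)
  tf <- rigid_transform(random_rotation_3d(), rnorm(3), 1.0)
  expect_equal(apply_transform(apply_transform(pose, tf), invert_transform(tf)),
               pose, tolerance = 1e-10)
  ts <- rigid_transform(random_rotation_3d(), rnorm(3), 1.7)
  expect_equal(apply_transform(apply_transform(pose, ts), invert_transform(ts)),
               pose, tolerance = 1e-10)
  # identity transform is a no-op; pure translation moves the centroid exactly
  id <- rigid_transform(diag(3), c(0, 0, 0))
  expect_identical(apply_transform(pose, id), pose)
  tt <- rigid_transform(diag(3), c(1, -2, 3))
  expect_equal(colMeans(apply_transform(pose, tt)), colMeans(pose) + c(1, -2, 3))
  expect_error(rigid_transform(diag(c(1, 1, -1)), rep(0, 3)),
               class = "ssmpose_model_error")
})

test_that("pairwise distance quartile behaves on degenerate and known inputs", {
  set.seed(7)
  base <- matrix(rnorm(15), 5, 3)
  # identical shapes under random motions -> quartile ~ 0
  coords <- array(NA_real_, c(12, 5, 3))
  for (i in 1:12)
    coords[i, , ] <- sweep(base %*% random_rotation_3d(), 2, rnorm(3), `+`)
  ds <- pose_dataset(coords)
  q <- pairwise_distance_quartile(ds, seed = 1)
  expect_lt(q, 1e-10)
  # invariant to a global rotation of the whole dataset
  R <- random_rotation_3d()
  coords2 <- coords
  for (i in 1:12) coords2[i, , ] <- coords[i, , ] %*% R
  expect_equal(pairwise_distance_quartile(pose_dataset(coords2), seed = 1), q,
               tolerance = 1e-10)

  # two well-separated clusters in equal proportion: the quartile equals the
  # within-cluster scale, verified against exhaustive enumeration
  set.seed(8)
  shapeA <- matrix(rnorm(15), 5, 3)
  shapeB <- shapeA + matrix(rnorm(15, sd = 4), 5, 3)
  coords3 <- array(NA_real_, c(20, 5, 3))
  for (i in 1:20) {
    s <- if (i <= 10) shapeA else shapeB
    coords3[i, , ] <- s + matrix(rnorm(15, sd = 0.05), 5, 3)
  }
  ds3 <- pose_dataset(coords3)
  q3 <- pairwise_distance_quartile(ds3, n_pairs = 1000, seed = 1)  # exhaustive: 190 pairs
  dists <- c()
  for (a in 1:19) for (b in (a + 1):20) {
    dists <- c(dists, procrustes_align(
      matrix(coords3[a, , ], 5, 3), matrix(coords3[b, , ], 5, 3))$residual)
  }
  expect_equal(q3, quantile(dists, 0.25, names = FALSE), tolerance = 1e-12)
  expect_lt(q3, 0.2)   # within-cluster scale, not the between-cluster distance
})
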
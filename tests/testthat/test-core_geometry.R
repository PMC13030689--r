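test_that("identity and pure-translation transforms behave trivially", {
  cl <- random_cloud(20, 1)
  out <- pm_apply_transform(cl, pm_transform())
  expect_equal(out$positions, cl$positions)

  pt <- pm_cloud(matrix(0, 1, 3))
  out <- pm_apply_transform(pt, pm_transform(diag(3), c(3, 4, 0)))
  expect_equal(as.numeric(out$positions), c(3, 4, 0))
})

test_that("rigid transforms preserve pairwise distances", {
  cl <- random_cloud(50, 2)
  R <- random_rotation(3)
  tf <- pm_transform(R, c(12, -7, 30))
  out <- pm_apply_transform(cl, tf)
  d0 <- dist(cl$positions)
  d1 <- dist(out$positions)
  expect_lt(max(abs(d1 - d0) / pmax(d0, 1e-12)), 1e-9)
})

test_that("non-orthonormal rotation is rejected when strict", {
  M <- diag(3) * 2
  expect_error(pm_transform(M), "invalid rotation")
  tf <- pm_transform(M, strict = FALSE)
  expect_error(pm_apply_transform(random_cloud(5, 4), tf), "invalid rotation")
  out <- pm_apply_transform(random_cloud(5, 4), tf, strict = FALSE)
  expect_equal(out$positions, random_cloud(5, 4)$positions * 2)
})

test_that("svd projection is idempotent on rotations and fixes scaling", {
  R <- random_rotation(5)
  expect_lt(max(abs(pm_svd_project(R) - R)), 1e-9)
  expect_equal(pm_svd_project(diag(c(2, 1, 1))), diag(3))
})

test_that("svd projection returns the Frobenius-closest rotation (random search oracle)", {
  for (seed in c(11, 12, 13)) {
    set.seed(seed)
    M <- matrix(rnorm(9), 3, 3)
    if (det(M) > 0) M[, 1] <- -M[, 1]  # exercise the det < 0 branch too
    R <- pm_svd_project(M)
    expect_true(pm_is_rotation(R))
    dR <- norm(M - R, "F")
    # dense random search over SO(3), including perturbations around R
    set.seed(seed + 100)
    for (i in 1:500) {
      cand <- if (i <= 250) {
        pm_svd_project(matrix(rnorm(9), 3, 3))
      } else {
        pm_svd_project(R + matrix(rnorm(9, 0, 0.05), 3, 3))
      }
      expect_gte(norm(M - cand, "F"), dR - 1e-8)
    }
  }
})

test_that("svd projection satisfies group invariants over many random matrices", {
  set.seed(42)
  for (i in 1:200) {
    R <- pm_svd_project(matrix(rnorm(9), 3, 3))
    expect_lt(norm(crossprod(R) - diag(3), "F"), 1e-6)
    expect_lt(abs(det(R) - 1), 1e-6)
  }
})

test_that("rank-deficient input to svd projection errors", {
  M <- outer(c(1, 0, 0), c(1, 0, 0))  # rank 1
  expect_error(pm_svd_project(M), "degenerate")
})

test_that("euler conventions: identity and single-axis rotations", {
  expect_equal(unname(pm_euler_from_rotation(diag(3))), c(0, 0, 0))
  Rz <- pm_rotation_from_euler(c(0, 0, 0.1))
  expect_equal(unname(pm_euler_from_rotation(Rz)), c(0, 0, 0.1), tolerance = 1e-12)
})

test_that("euler round trip is exact away from gimbal lock", {
  set.seed(7)
  worst <- 0
  for (i in 1:100) {
    a <- runif(3, -pi, pi)
    a[2] <- runif(1, -pi / 2 + 0.01, pi / 2 - 0.01)
    R <- pm_rotation_from_euler(a)
    R2 <- pm_rotation_from_euler(pm_euler_from_rotation(R))
    worst <- max(worst, max(abs(R2 - R)))
  }
  expect_lt(worst, 1e-8)
})

test_that("gimbal lock uses the documented tie-break without error", {
  R <- pm_rotation_from_euler(c(0.4, pi / 2, 0.2))
  a <- pm_euler_from_rotation(R)
  expect_equal(unname(a[3]), 0)
  # decomposition still reproduces the rotation
  expect_lt(max(abs(pm_rotation_from_euler(a) - R)), 1e-6)
})

test_that("canonicalization restores the canonical invariants", {
  lm <- canonical_landmarks(dy = 6)
  # already canonical: identity transform
  tf <- pm_canonicalize_pose(lm)
  expect_lt(max(abs(tf$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(tf$translation)), 1e-9)

  # known rotation + shift is recovered
  Rf <- pm_rotation_from_euler(c(7, 15, 0) * pi / 180)
  moved <- pm_apply_transform(lm, pm_transform(Rf, c(40, -12, 88)))
  tf2 <- pm_canonicalize_pose(moved)
  m <- unclass(pm_apply_transform(moved, tf2))
  expect_lt(max(abs((m["PSIS_L", ] + m["PSIS_R", ]) / 2)), 1e-6)
  expect_lt(abs(m["PSIS_L", 3] - m["PSIS_R", 3]), 1e-6)
  expect_lt(abs(m["L4", 3]), 1e-6)
  expect_gt(m["PSIS_R", 1], 0)
})

test_that("canonicalization recovers 100 seeded random poses", {
  for (i in 1:100) {
    set.seed(i)
    lm <- canonical_landmarks(dy = runif(1, -10, 10))
    ang <- runif(3, -0.6, 0.6)
    tf_in <- pm_transform(pm_rotation_from_euler(ang), runif(3, -200, 200))
    moved <- pm_apply_transform(lm, tf_in)
    m <- unclass(pm_apply_transform(moved, pm_canonicalize_pose(moved)))
    expect_lt(max(abs((m["PSIS_L", ] + m["PSIS_R", ]) / 2)), 1e-6)
    expect_lt(abs(m["PSIS_L", 3] - m["PSIS_R", 3]), 1e-6)
    expect_lt(abs(m["L4", 3]), 1e-6)
  }
})

test_that("canonicalization is idempotent", {
  set.seed(9)
  lm <- canonical_landmarks(dy = 4)
  moved <- pm_apply_transform(lm, pm_transform(random_rotation(21), c(5, 5, 5)))
  once <- pm_apply_transform(moved, pm_canonicalize_pose(moved))
  tf2 <- pm_canonicalize_pose(once)
  expect_lt(max(abs(tf2$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(tf2$translation)), 1e-6)
})

test_that("canonicalization rejects degenerate or incomplete landmark sets", {
  lm <- pm_landmarks(list(PSIS_L = c(-40, 0, 0), PSIS_R = c(40, 0, 0)))
  expect_error(pm_canonicalize_pose(lm), "missing landmark")
  bad <- pm_landmarks(list(PSIS_L = c(0, 0, 0), PSIS_R = c(0, 0, 0),
                           L4 = c(0, 60, 0)))
  expect_error(pm_canonicalize_pose(bad), "degenerate")
})

test_that("transform JSON round trip preserves rotation and translation", {
  tf <- pm_transform(random_rotation(31), c(1.5, -2.25, 100))
  js <- pm_transform_to_json(tf)
  tf2 <- pm_transform_from_json(js)
  expect_equal(tf2$rotation, tf$rotation)
  expect_equal(tf2$translation, tf$translation)
  p <- withr::local_tempfile(fileext = ".json")
  pm_transform_to_json(tf, p)
  expect_equal(pm_transform_from_json(p)$rotation, tf$rotation)
})

test_that("transform composition and inversion are consistent", {
  a <- pm_transform(random_rotation(41), c(1, 2, 3))
  b <- pm_transform(random_rotation(42), c(-5, 0, 9))
  cl <- random_cloud(10, 43)
  via_compose <- pm_apply_transform(cl, pm_transform_compose(a, b))
  via_seq <- pm_apply_transform(pm_apply_transform(cl, b), a)
  expect_equal(via_compose$positions, via_seq$positions)
  inv <- pm_transform_inverse(a)
  back <- pm_apply_transform(pm_apply_transform(cl, a), inv)
  expect_equal(back$positions, cl$positions, tolerance = 1e-12)
})
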
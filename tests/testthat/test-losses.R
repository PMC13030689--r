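# Every objective is checked against an explicit double-loop summation
# oracle on seeded random instances, plus its closed-form spot values.

oracle_nll <- function(logp, y, w) {
  tot <- 0
  for (i in seq_len(nrow(logp))) {
    tot <- tot + w[y[i] + 1] * logp[i, y[i] + 1]
  }
  -tot / nrow(logp)
}

random_logp <- function(n, C, seed) {
  set.seed(seed)
  Z <- matrix(rnorm(n * C), n, C)
  Z - log(rowSums(exp(Z)))
}

test_that("weighted NLL matches the summation oracle and closed forms", {
  # uniform 2-class predictions -> ln 2
  logp <- matrix(log(0.5), 4, 2)
  expect_equal(pm_nll_loss(logp, c(0, 1, 0, 1)), log(2), tolerance = 1e-12)
  # (near-)one-hot predictions -> ~0
  hot <- log(matrix(c(1 - 1e-12, 1e-12), 3, 2, byrow = TRUE))
  expect_equal(pm_nll_loss(hot, c(0, 0, 0)), 0, tolerance = 1e-9)
  # random cases, including the printed 10 x 3 weighted case
  for (seed in 1:20) {
    n <- 10; C <- 3
    logp <- random_logp(n, C, seed)
    set.seed(seed + 50)
    y <- sample(0:(C - 1), n, replace = TRUE)
    w <- c(1, 2, 0.5)
    expect_equal(pm_nll_loss(logp, y, w), oracle_nll(logp, y, w),
                 tolerance = 1e-10)
  }
})

test_that("NLL rejects mismatched shapes and out-of-range labels", {
  logp <- random_logp(5, 3, 1)
  expect_error(pm_nll_loss(logp, c(0, 1)), "length")
  expect_error(pm_nll_loss(logp, c(0, 1, 2, 3, 0)), "out of range")
})

test_that("point-set distance matches the per-point norm oracle", {
  a <- random_cloud(30, 1)
  expect_equal(pm_point_set_distance(a, a), 0)
  shifted <- a
  shifted$positions <- sweep(a$positions, 2, c(3, 4, 0), "+")
  expect_equal(pm_point_set_distance(shifted, a), 5, tolerance = 1e-12)
  for (seed in 1:20) {
    b <- random_cloud(30, seed + 200)
    oracle <- mean(vapply(seq_len(30), function(i) {
      sqrt(sum((a$positions[i, ] - b$positions[i, ])^2))
    }, numeric(1)))
    expect_equal(pm_point_set_distance(a, b), oracle, tolerance = 1e-10)
  }
  expect_error(pm_point_set_distance(a, random_cloud(10, 3)), "match")
})

test_that("rotation regularizer: zero on the orthogonal group, 3*sqrt(3) at 2I", {
  expect_equal(pm_rotation_regularization(diag(3)), 0)
  expect_equal(pm_rotation_regularization(2 * diag(3)), 3 * sqrt(3),
               tolerance = 1e-12)
  R <- random_rotation(5)
  expect_lt(pm_rotation_regularization(R), 1e-12)
  reflection <- diag(c(1, 1, -1))  # det -1: still zero, exclusion is the SVD's job
  expect_lt(pm_rotation_regularization(reflection), 1e-12)
  for (seed in 1:20) {
    set.seed(seed)
    M <- matrix(rnorm(9), 3, 3)
    E <- diag(3) - t(M) %*% M
    expect_equal(pm_rotation_regularization(M), sqrt(sum(E^2)),
                 tolerance = 1e-10)
  }
})

test_that("euler-angle loss matches the conversion-then-norm oracle", {
  R <- random_rotation(8)
  expect_equal(pm_euler_angle_loss(R, R), 0)
  expect_equal(pm_euler_angle_loss(pm_rotation_from_euler(c(0, 0, 0.1)), diag(3)),
               0.1, tolerance = 1e-12)
  for (seed in 1:20) {
    Ra <- random_rotation(seed + 300)
    Rb <- random_rotation(seed + 600)
    oracle <- sqrt(sum((pm_euler_from_rotation(Ra) - pm_euler_from_rotation(Rb))^2))
    expect_equal(pm_euler_angle_loss(Ra, Rb), oracle, tolerance = 1e-8)
  }
})

test_that("alignment total loss recombines its three terms", {
  a <- random_cloud(25, 2)
  w <- pm_loss_weights(lambda_rot = 0.3, lambda_euler = 0.7)
  # lambda 0: reduces to the point term
  w0 <- pm_loss_weights(lambda_rot = 0, lambda_euler = 0)
  b <- random_cloud(25, 3)
  expect_equal(as.numeric(pm_align_total_loss(a, b, diag(3), diag(3), w0)),
               pm_point_set_distance(a, b))
  # perfect prediction -> 0
  expect_equal(as.numeric(pm_align_total_loss(a, a, diag(3), diag(3), w)), 0)
  for (seed in 1:20) {
    set.seed(seed)
    M <- diag(3) + matrix(rnorm(9, 0, 0.2), 3, 3)
    Rref <- random_rotation(seed + 900)
    tot <- pm_align_total_loss(a, b, M, Rref, w)
    oracle <- pm_point_set_distance(a, b) +
      0.3 * pm_rotation_regularization(M) +
      0.7 * pm_euler_angle_loss(pm_svd_project(M), Rref)
    expect_equal(as.numeric(tot), oracle, tolerance = 1e-10)
    expect_equal(attr(tot, "pts") + 0.3 * attr(tot, "rot") +
                   0.7 * attr(tot, "euler"), oracle, tolerance = 1e-10)
  }
})

test_that("marker distance loss averages over ground-truth-present markers", {
  gt <- random_landmarks(4)
  expect_equal(pm_marker_distance_loss(gt, gt), 0)
  # one of six offset by 6 mm -> mean 1 mm
  pred <- unclass(gt)
  pred["L1", ] <- pred["L1", ] + c(6, 0, 0)
  expect_equal(pm_marker_distance_loss(pm_landmarks(pred), gt), 1)
  # three markers, offsets 1/2/3 -> 2
  gt3 <- pm_landmarks(list(PSIS_L = c(0, 0, 0), PSIS_R = c(100, 0, 0),
                           L4 = c(50, 60, 0)))
  pr3 <- pm_landmarks(list(PSIS_L = c(1, 0, 0), PSIS_R = c(100, 2, 0),
                           L4 = c(50, 60, 3)))
  expect_equal(pm_marker_distance_loss(pr3, gt3), 2)
  # unpredicted marker present in gt draws the documented penalty
  pr_miss <- pm_landmarks(list(PSIS_L = c(0, 0, 0), PSIS_R = c(100, 0, 0)))
  expect_equal(pm_marker_distance_loss(pr_miss, gt3, missing_penalty_mm = 50),
               50 / 3)
  expect_error(pm_marker_distance_loss(gt, pm_landmarks(list())), "valid markers")
})

test_that("landmark total loss recombines NLL and distance terms", {
  gt <- random_landmarks(6)
  for (seed in 1:20) {
    logp <- random_logp(40, 7, seed)
    set.seed(seed)
    y <- sample(0:6, 40, replace = TRUE)
    pred <- random_landmarks(seed + 70)
    w <- pm_loss_weights(lambda_dist = 10)
    tot <- pm_landmark_total_loss(logp, y, pred, gt, w)
    oracle <- pm_nll_loss(logp, y) + 10 * pm_marker_distance_loss(pred, gt)
    expect_equal(as.numeric(tot), oracle, tolerance = 1e-10)
  }
  # lambda_dist = 0 reduces to the NLL
  logp <- random_logp(10, 7, 1)
  y <- rep(0L, 10)
  w0 <- pm_loss_weights(lambda_dist = 0)
  expect_equal(as.numeric(pm_landmark_total_loss(logp, y, gt, gt, w0)),
               pm_nll_loss(logp, y))
})

test_that("losses are non-negative and zero at their perfect-prediction case", {
  logp <- log(matrix(c(1 - 1e-12, rep(1e-12 / 6, 6)), 5, 7, byrow = TRUE))
  expect_gte(pm_nll_loss(random_logp(10, 4, 1), rep(1L, 10)), 0)
  expect_lt(pm_nll_loss(logp, rep(0L, 5)), 1e-9)
  lm <- random_landmarks(3)
  expect_equal(pm_marker_distance_loss(lm, lm), 0)
  expect_equal(pm_euler_angle_loss(diag(3), diag(3)), 0)
})

test_that("analytic loss gradients pass finite-difference checks", {
  # NLL gradient w.r.t. log-probabilities
  set.seed(11)
  Z <- matrix(rnorm(8 * 3), 8, 3)
  y <- sample(0:2, 8, replace = TRUE)
  w <- c(1, 2, 0.5)
  logp <- Z - log(rowSums(exp(Z)))
  g <- pelvimark:::nll_with_grad(logp, y, w)
  h <- 1e-6
  for (i in sample(length(Z), 6)) {
    Zp <- Z; Zp[i] <- Zp[i] + h
    Zm <- Z; Zm[i] <- Zm[i] - h
    fd <- (pm_nll_loss(Zp - log(rowSums(exp(Zp))), y, w) -
             pm_nll_loss(Zm - log(rowSums(exp(Zm))), y, w)) / (2 * h)
    an <- pelvimark:::log_softmax_bwd(logp, g$dlogp)[i]
    expect_equal(an, fd, tolerance = 1e-4)
  }
  # rotation regularizer gradient w.r.t. the raw matrix
  set.seed(12)
  M <- diag(3) + matrix(rnorm(9, 0, 0.3), 3, 3)
  gr <- pelvimark:::rotation_reg_grad(M)
  for (i in 1:9) {
    Mp <- M; Mp[i] <- Mp[i] + h
    Mm <- M; Mm[i] <- Mm[i] - h
    fd <- (pm_rotation_regularization(Mp) - pm_rotation_regularization(Mm)) / (2 * h)
    expect_equal(gr$dR[i], fd, tolerance = 1e-4)
  }
  # soft-centre distance gradient w.r.t. logits (through log-softmax)
  set.seed(13)
  Z <- matrix(rnorm(30 * 7), 30, 7)
  pos <- matrix(runif(90, -50, 50), 30, 3)
  gt <- random_landmarks(14, spread = 40)
  lsm <- function(Z) Z - log(rowSums(exp(Z)))
  r <- pelvimark:::soft_center_loss_grad(lsm(Z), pos, gt)
  dz <- pelvimark:::log_softmax_bwd(lsm(Z), r$dlogp)
  for (i in sample(length(Z), 8)) {
    Zp <- Z; Zp[i] <- Zp[i] + h
    Zm <- Z; Zm[i] <- Zm[i] - h
    fd <- (pelvimark:::soft_center_loss_grad(lsm(Zp), pos, gt)$loss -
             pelvimark:::soft_center_loss_grad(lsm(Zm), pos, gt)$loss) / (2 * h)
    expect_equal(dz[i], fd, tolerance = 1e-4)
  }
})

test_that("the svd-projection backward matches finite differences", {
  set.seed(15)
  for (rep in 1:5) {
    M <- diag(3) + matrix(rnorm(9, 0, 0.25), 3, 3)
    W <- matrix(rnorm(9), 3, 3)
    G <- pelvimark:::svd_project_bwd(M, W)
    h <- 1e-6
    for (i in sample(9, 4)) {
      Mp <- M; Mp[i] <- Mp[i] + h
      Mm <- M; Mm[i] <- Mm[i] - h
      fd <- (sum(pm_svd_project(Mp) * W) - sum(pm_svd_project(Mm) * W)) / (2 * h)
      expect_equal(G[i], fd, tolerance = 1e-4)
    }
  }
})

test_that("soft centres match the probability-weighted oracle", {
  logp <- random_logp(50, 7, 21)
  set.seed(21)
  pos <- matrix(runif(150, -80, 80), 50, 3)
  sc <- unclass(pm_soft_centers(logp, pos))
  p <- exp(logp)
  for (k in 1:6) {
    oracle <- colSums(pos * p[, k + 1]) / sum(p[, k + 1])
    expect_equal(unname(sc[k, ]), oracle, tolerance = 1e-12)
  }
})
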
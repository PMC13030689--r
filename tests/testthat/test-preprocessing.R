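test_that("ROI box bounds are the landmark bounding box plus the margin", {
  lm <- pm_landmarks(list(PSIS_L = c(-50, 0, 10), PSIS_R = c(60, 5, -20)))
  box <- pm_roi_box(lm, 100)
  expect_equal(unname(box["x", ]), c(-150, 160))
  expect_equal(unname(box["y", ]), c(-100, 105))
  expect_equal(unname(box["z", ]), c(-120, 110))
  one <- pm_roi_box(pm_landmarks(list(L1 = c(0, 0, 0))), 100)
  expect_equal(unname(unclass(one)), cbind(rep(-100, 3), rep(100, 3)))
  tight <- pm_roi_box(lm, 0)
  expect_equal(unname(tight["x", ]), c(-50, 60))
  expect_error(pm_roi_box(pm_landmarks(list())), "empty")
})

test_that("ROI box is translation-equivariant", {
  set.seed(1)
  lm <- random_landmarks(2)
  v <- c(17, -8, 120)
  shifted <- pm_landmarks(unclass(lm) + rep(v, each = 6))
  b0 <- pm_roi_box(lm)
  b1 <- pm_roi_box(shifted)
  expect_equal(unclass(b1), unclass(b0) + cbind(v, v), tolerance = 1e-12)
})

test_that("in-box labeling is closed and matches a per-axis oracle", {
  box <- pm_box(cbind(c(-10, -10, -10), c(10, 20, 30)))
  corner <- pm_cloud(matrix(c(10, 20, 30), 1, 3))
  expect_equal(as.integer(pm_label_in_box(corner, box)), 1L)
  inside <- pm_cloud(matrix(runif(30, -5, 5), 10, 3))
  expect_true(all(as.integer(pm_label_in_box(inside, box)) == 1L))
  set.seed(3)
  cl <- random_cloud(1000, 3, range = 40)
  lab <- as.integer(pm_label_in_box(cl, box))
  oracle <- apply(cl$positions, 1, function(p) {
    as.integer(p[1] >= -10 && p[1] <= 10 && p[2] >= -10 && p[2] <= 20 &&
                 p[3] >= -10 && p[3] <= 30)
  })
  expect_equal(lab, oracle)
})

test_that("landmark-region labels: radius, boundary and nearest-marker ties", {
  lm <- pm_landmarks(list(PSIS_L = c(0, 0, 0), L1 = c(0, 100, 0),
                          L4 = c(0, 50, 0)))
  pts <- pm_cloud(rbind(c(9.9, 0, 0),      # 9.9 mm from PSIS_L -> class 1
                        c(0, 10.1, 0),     # >10 mm from everything -> 0
                        c(0, 10, 0),       # exactly 10 mm -> inside (closed)
                        c(0, 56, 0)))      # 6 mm from L4, 44 from L1 -> L4
  lab <- as.integer(pm_label_landmark_regions(pts, lm, 10))
  expect_equal(lab, c(1L, 0L, 1L, 6L))

  # tie region between two 10 mm spheres: nearest marker wins
  lm2 <- pm_landmarks(list(L1 = c(0, 0, 0), L4 = c(0, 14, 0)))
  probe <- pm_cloud(rbind(c(0, 6, 0), c(0, 8, 0)))
  expect_equal(as.integer(pm_label_landmark_regions(probe, lm2, 10)), c(5L, 6L))
})

test_that("landmark-region labels match a brute-force distance oracle", {
  set.seed(5)
  lm <- random_landmarks(5, spread = 60)
  cl <- random_cloud(1000, 6, range = 80)
  lab <- as.integer(pm_label_landmark_regions(cl, lm, 25))
  m <- unclass(lm)
  oracle <- apply(cl$positions, 1, function(p) {
    d <- sqrt(colSums((t(m) - p)^2))
    if (min(d) <= 25) which.min(d) else 0L
  })
  expect_equal(lab, as.integer(oracle))
  # invariant: every labeled point is within radius of its marker
  for (k in 1:6) {
    idx <- which(lab == k)
    if (length(idx)) {
      d <- sqrt(rowSums(sweep(cl$positions[idx, , drop = FALSE], 2, m[k, ])^2))
      expect_true(all(d <= 25))
    }
  }
})

test_that("uniform downsampling is a seeded subset without replacement", {
  cl <- random_cloud(5000, 7)
  lab <- pm_labels(rep_len(c(0L, 1L), 5000), 2L)
  out <- pm_downsample(cl, 1200, seed = 9, labels = lab)
  expect_equal(pm_n_points(out$cloud), 1200L)
  expect_equal(length(out$labels), 1200L)
  expect_false(any(duplicated(out$idx)))
  expect_true(all(out$idx %in% seq_len(5000)))
  expect_equal(out$cloud$positions, cl$positions[out$idx, ])
  expect_equal(as.integer(out$labels), as.integer(lab)[out$idx])
  # determinism
  again <- pm_downsample(cl, 1200, seed = 9, labels = lab)
  expect_identical(out$idx, again$idx)
  # n = cloud size is a permutation
  perm <- pm_downsample(cl, 5000, seed = 1)
  expect_equal(sort(perm$positions[, 1]), sort(cl$positions[, 1]))
  expect_error(pm_downsample(cl, 6000), "insufficient")
})

test_that("point features: raw channels plus min-max normalization", {
  P <- rbind(c(0, -10, 5), c(100, 10, 5), c(25, 0, 5))
  cl <- pm_point_features(pm_cloud(P))
  F <- cl$features
  expect_equal(ncol(F), 6L)
  expect_equal(unname(F[, 1:3]), P)
  expect_equal(unname(F[3, 4]), 0.25)     # x = 25 on [0, 100]
  expect_equal(unname(F[, 6]), rep(0.5, 3))  # degenerate z axis
  expect_true(all(F[, 4:6] >= 0 & F[, 4:6] <= 1))
  same <- pm_point_features(pm_cloud(matrix(1, 5, 3)))
  expect_true(all(same$features[, 4:6] == 0.5))
})

test_that("augmentation yields factor samples with recorded invertible rotations", {
  cl <- random_cloud(200, 8)
  lab <- pm_labels(rep_len(0:1, 200), 2L)
  lm <- random_landmarks(8)
  cfg <- pm_augment_config(rotation_range_deg = 20, factor = 5, seed = 3)
  aug <- pm_augment(cl, lab, lm, cfg)
  expect_length(aug, 5L)
  ctr <- colMeans(cl$positions)
  for (a in aug) {
    expect_equal(pm_n_points(a$cloud), 200L)
    expect_identical(as.integer(a$labels), as.integer(lab))
    expect_true(all(abs(a$angles_deg) <= 20))
    # inverting the recorded rotation restores the centred coordinates
    undone <- a$cloud$positions %*% t(a$correction)
    expect_lt(max(abs(undone - sweep(cl$positions, 2, ctr))), 1e-9)
    # landmarks transformed identically
    lm_undone <- unclass(a$landmarks) %*% t(a$correction)
    expect_lt(max(abs(lm_undone - sweep(unclass(lm), 2, ctr))), 1e-9)
    # rigid: pairwise distances preserved
    expect_lt(max(abs(dist(a$cloud$positions) - dist(cl$positions))), 1e-8)
  }
  # zero range: centroid-translated copies
  still <- pm_augment(cl, cfg = pm_augment_config(0, 3, seed = 2))
  for (a in still) {
    expect_lt(max(abs(a$cloud$positions - sweep(cl$positions, 2, ctr))), 1e-12)
  }
  # determinism of the seed stream
  again <- pm_augment(cl, lab, lm, cfg)
  expect_identical(aug[[3]]$rotation, again[[3]]$rotation)
})

test_that("manual-crop simulation draws offsets in range and keeps landmarks", {
  scan <- tiny_scans()[[1]]
  # degenerate interval equals the fixed-margin ROI box
  cr <- pm_simulate_manual_crop(scan$cloud, scan$landmarks, lo = 100, hi = 100,
                                seed = 4)
  expect_equal(unclass(cr$box), unclass(pm_roi_box(scan$landmarks, 100)),
               tolerance = 1e-12)
  # offsets within [50, 150] over many seeded draws
  for (seed in 1:200) {
    cr <- pm_simulate_manual_crop(scan$cloud, scan$landmarks, seed = seed)
    expect_true(all(cr$offsets >= 50 & cr$offsets <= 150))
    # all six landmarks inside the crop box (offsets >= 50 > label radius)
    m <- unclass(scan$landmarks)
    expect_true(all(m[, 1] >= cr$box[1, 1] & m[, 1] <= cr$box[1, 2] &
                      m[, 2] >= cr$box[2, 1] & m[, 2] <= cr$box[2, 2] &
                      m[, 3] >= cr$box[3, 1] & m[, 3] <= cr$box[3, 2]))
  }
  # determinism
  a <- pm_simulate_manual_crop(scan$cloud, scan$landmarks, seed = 77)
  b <- pm_simulate_manual_crop(scan$cloud, scan$landmarks, seed = 77)
  expect_identical(a$idx, b$idx)
})
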
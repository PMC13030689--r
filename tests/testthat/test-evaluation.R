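test_that("IoU and recall match the confusion-matrix oracle", {
  gt <- pm_labels(rep(c(0L, 1L), c(50, 50)), 2L)
  perfect <- pm_iou_recall(gt, gt)
  expect_equal(perfect$iou, c(1, 1))
  expect_equal(perfect$recall, c(1, 1))
  # 80 TP, 10 FP, 10 FN for class 1
  pred <- c(rep(0L, 40), rep(1L, 10), rep(0L, 10), rep(1L, 80))
  truth <- c(rep(0L, 50), rep(1L, 90))
  r <- pm_iou_recall(pm_labels(pred, 2L), pm_labels(truth, 2L))
  expect_equal(r$iou[2], 0.8)
  expect_equal(r$recall[2], 80 / 90)
  # random case against explicit set operations
  set.seed(4)
  p <- sample(0:2, 500, replace = TRUE)
  g <- sample(0:2, 500, replace = TRUE)
  r <- pm_iou_recall(pm_labels(p, 3L), pm_labels(g, 3L))
  for (cl in 0:2) {
    tp <- sum(p == cl & g == cl); fp <- sum(p == cl & g != cl)
    fn <- sum(p != cl & g == cl)
    expect_equal(r$iou[cl + 1], tp / (tp + fp + fn))
    expect_equal(r$recall[cl + 1], tp / (tp + fn))
  }
  # class absent from both -> missing
  r2 <- pm_iou_recall(pm_labels(rep(0L, 10), 3L), pm_labels(rep(0L, 10), 3L))
  expect_true(is.na(r2$iou[2]) && is.na(r2$recall[3]))
  expect_true(all(r$iou <= 1 & r$recall <= 1, na.rm = TRUE))
})

test_that("localization errors are per-landmark Euclidean distances", {
  gt <- random_landmarks(1)
  same <- pm_localization_errors(gt, gt)
  expect_equal(same$error_mm, rep(0, 6))
  off <- unclass(gt)
  off["IC_L", ] <- off["IC_L", ] + c(3, 4, 0)
  r <- pm_localization_errors(pm_landmarks(off), gt)
  expect_equal(r$error_mm[r$landmark == "IC_L"], 5)
  expect_equal(sum(r$error_mm), 5)
  # random sets against the norm oracle
  for (seed in 1:10) {
    a <- random_landmarks(seed + 10)
    b <- random_landmarks(seed + 20)
    r <- pm_localization_errors(a, b)
    oracle <- sqrt(rowSums((unclass(a) - unclass(b))^2))
    expect_equal(r$error_mm, unname(oracle), tolerance = 1e-12)
  }
  # missing prediction flagged, not silently dropped
  miss <- unclass(gt); miss["L1", ] <- NA
  r <- pm_localization_errors(pm_landmarks(miss), gt)
  expect_true(r$missing[r$landmark == "L1"])
  expect_true(is.na(r$error_mm[r$landmark == "L1"]))
})

test_that("error summaries: medians, subject-level mean and CDF", {
  errors <- tibble::tibble(error_mm = c(1, 2, 3),
                           subject_id = rep("A", 3),
                           landmark = c("L1", "L4", "PSIS_L"))
  rep1 <- pm_summarize_errors(errors)
  expect_equal(rep1$median_mm, 2)
  expect_equal(rep1$subject_mean_mm, 2)
  # two subjects with means 10 and 20 -> unweighted subject mean 15
  errors2 <- tibble::tibble(error_mm = c(10, 10, 20),
                            subject_id = c("A", "A", "B"))
  rep2 <- pm_summarize_errors(errors2)
  expect_equal(rep2$subject_mean_mm, 15)
  # CDF properties
  expect_true(all(diff(rep2$cdf$fraction) >= 0))
  expect_lte(max(rep2$cdf$fraction), 1)
  expect_equal(rep2$cdf$fraction[rep2$cdf$threshold_mm == 20], 1)
  # median invariant under permutation
  set.seed(1)
  e <- runif(40, 0, 30)
  t1 <- pm_summarize_errors(tibble::tibble(error_mm = e, subject_id = "S"))
  t2 <- pm_summarize_errors(tibble::tibble(error_mm = sample(e), subject_id = "S"))
  expect_equal(t1$median_mm, t2$median_mm)
})

test_that("subject-level t-interval covers the truth about 95% of the time", {
  set.seed(77)
  n_subj <- 8
  truth <- 12
  cover <- 0
  nsim <- 500
  for (i in 1:nsim) {
    means <- rnorm(n_subj, truth, 2)
    errors <- tibble::tibble(error_mm = means,
                             subject_id = sprintf("S%d", seq_len(n_subj)))
    ci <- pm_summarize_errors(errors)$subject_ci_mm
    if (ci[1] <= truth && truth <= ci[2]) cover <- cover + 1
  }
  expect_gt(cover / nsim, 0.92)
  expect_lt(cover / nsim, 0.98)
})

test_that("paired distances follow the three measurement regions", {
  lm <- pm_landmarks(list(PSIS_L = c(-50, 0, 0), PSIS_R = c(50, 0, 0),
                          IC_L = c(-130, 40, 0), IC_R = c(130, 40, 0),
                          L1 = c(0, 215, 0), L4 = c(0, 65, 0)))
  rec <- list(list(landmarks = lm, subject_id = "A", visit = 1, rep = 1))
  s <- pm_paired_distance_series(rec)
  expect_equal(s$distance_mm[s$region == "PSIS_L-PSIS_R"], 100)
  expect_equal(s$distance_mm[s$region == "IC_L-IC_R"], 260)
  expect_equal(s$distance_mm[s$region == "L1-L4"], 150)
  # missing landmark -> missing distance for that region only
  m2 <- unclass(lm); m2["IC_R", ] <- NA
  rec2 <- list(list(landmarks = pm_landmarks(m2), subject_id = "A",
                    visit = 1, rep = 2))
  s2 <- pm_paired_distance_series(rec2)
  expect_true(is.na(s2$distance_mm[s2$region == "IC_L-IC_R"]))
  expect_equal(sum(is.na(s2$distance_mm)), 1L)
  # random sets against the norm oracle
  lmr <- random_landmarks(3)
  s3 <- pm_paired_distance_series(list(list(landmarks = lmr, subject_id = "B",
                                            visit = 1, rep = 1)))
  m <- unclass(lmr)
  expect_equal(s3$distance_mm[s3$region == "L1-L4"],
               sqrt(sum((m["L1", ] - m["L4", ])^2)))
})

make_series <- function(values) {
  # values: matrix units x repeats for a single region
  rows <- list()
  for (u in seq_len(nrow(values))) for (r in seq_len(ncol(values))) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      subject_id = sprintf("S%d", u), visit = 1, rep = r,
      region = "PSIS_L-PSIS_R", distance_mm = values[u, r])
  }
  do.call(rbind, rows)
}

test_that("repeatability degenerate cases behave as documented", {
  # identical repeats within subject, subjects differ -> ICC 1, CV 0
  x <- matrix(rep(c(100, 110, 120, 130), each = 3), 4, 3, byrow = TRUE)
  r <- pm_repeatability(make_series(x))
  expect_equal(r$icc, 1)
  expect_equal(r$cv_pct, 0)
  expect_equal(r$std_mm, 0)
  expect_true(r$icc_lo <= r$icc && r$icc <= r$icc_hi)
  # all values equal everywhere -> zero variance, ICC missing
  x0 <- matrix(100, 4, 3)
  r0 <- pm_repeatability(make_series(x0))
  expect_equal(r0$std_mm, 0)
  expect_equal(r0$cv_pct, 0)
  expect_true(is.na(r0$icc))
})

test_that("ICC recovers the variance-component ratio on simulated data", {
  set.seed(303)
  n <- 200; k <- 3
  subj_eff <- rnorm(n, 0, 3)         # sigma^2_between = 9
  x <- matrix(rnorm(n * k, 0, 1), n, k) + subj_eff + 100  # sigma^2_within = 1
  r <- pm_repeatability(make_series(x))
  expect_lt(abs(r$icc - 0.9), 0.03)
  expect_true(r$icc_lo <= r$icc && r$icc <= r$icc_hi)
  expect_true(r$icc >= -1 && r$icc <= 1)
  # pooled within STD near 1 and CV near 1%
  expect_lt(abs(r$std_mm - 1), 0.1)
  expect_lt(abs(r$cv_pct - 1), 0.15)
})

test_that("ICC tolerance shrinks as the subject count grows", {
  errs <- sapply(c(40, 400), function(n) {
    set.seed(500 + n)
    reps <- replicate(20, {
      subj_eff <- rnorm(n, 0, 3)
      x <- matrix(rnorm(n * 3), n, 3) + subj_eff + 50
      pm_repeatability(make_series(x))$icc
    })
    mean(abs(reps - 0.9))
  })
  expect_lt(errs[2], errs[1])
})

test_that("ICC(3,1) consistency form is available by flag", {
  set.seed(9)
  x <- matrix(rnorm(60), 20, 3) + rnorm(20, 0, 3)
  # add a constant rater offset: ICC3 (consistency) should exceed ICC2
  x[, 2] <- x[, 2] + 2
  r2 <- pm_repeatability(make_series(x), type = "ICC2")
  r3 <- pm_repeatability(make_series(x), type = "ICC3")
  expect_gt(r3$icc, r2$icc)
})

test_that("unbalanced repeat counts are truncated to a balanced layout", {
  s <- make_series(matrix(c(10, 11, 12, 20, 21, 22), 2, 3, byrow = TRUE))
  extra <- tibble::tibble(subject_id = "S3", visit = 1, rep = 1:2,
                          region = "PSIS_L-PSIS_R", distance_mm = c(30, 31))
  r <- pm_repeatability(rbind(s, extra))
  expect_equal(r$k_repeats, 2L)
  expect_equal(r$n_units, 3L)
  expect_false(is.na(r$icc))
})

test_that("report plots and exports produce the expected artifacts", {
  errors <- tibble::tibble(error_mm = runif(30, 2, 25),
                           subject_id = rep(c("A", "B", "C"), 10),
                           landmark = rep(pm_landmark_names(), 5))
  rep <- pm_summarize_errors(errors)
  expect_s3_class(autoplot(rep), "ggplot")
  errors$arm <- "full"
  expect_s3_class(pm_plot_error_cdf(errors), "ggplot")
  hist <- tibble::tibble(epoch = 1:3, train_loss = c(3, 2, 1),
                         val_loss = c(3.2, 2.4, 1.5))
  expect_s3_class(pm_plot_history(hist), "ggplot")
  stem <- file.path(withr::local_tempdir(), "report")
  paths <- pm_export_report(rep, stem)
  expect_true(all(file.exists(paste0(stem, c(".csv", "_cdf.csv", ".json")))))
  long <- utils::read.csv(paste0(stem, ".csv"))
  expect_true(all(c("metric", "group", "value") %in% names(long)))
  cdf <- utils::read.csv(paste0(stem, "_cdf.csv"))
  expect_equal(ncol(cdf), 2L)
})

test_that("sensitivity grid covers the five settings and reproduces bitwise", {
  scans <- tiny_scans()[1:4]
  cfg <- pm_train_config(epochs = 2L, batch_size = 4L, preset = "tiny",
                         downsample_n = 400L, augment_factor = 1L, seed = 9)
  grid <- pm_sensitivity_grid(scans[1:3], scans[4], cfg, seed = 3)
  # 3 loss weights at the reference radius + 2 further radii at the
  # reference weight: 5 settings with the shared centre counted once
  expect_equal(nrow(grid), 5L)
  expect_equal(sum(grid$parameter == "lambda_dist"), 3L)
  expect_equal(sort(grid$lambda_dist[grid$parameter == "lambda_dist"]),
               c(5, 10, 15))
  expect_equal(sort(grid$radius_mm[grid$parameter == "radius_mm"]), c(15, 20))
  expect_true(all(c("parameter", "value", "mean_error_mm") %in% names(grid)))
  expect_true(all(is.finite(grid$mean_error_mm)))
  grid2 <- pm_sensitivity_grid(scans[1:3], scans[4], cfg, seed = 3)
  expect_identical(grid, grid2)
})
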
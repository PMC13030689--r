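#' Run the scaled-down synthetic recovery study
#'
#' Generates a synthetic cohort, trains the three pipeline networks plus the
#' baseline landmark network on the training subjects (tiny preset,
#' 2048-point clouds), and measures: held-out ROI IoU/recall, median
#' recovered-rotation error, held-out landmark-centre errors, and the
#' five-arm ablation error table. This is the package's reference
#' experiment: deterministic given `seed`, sized to run in minutes on one
#' CPU.
#'
#' @param seed master seed for data generation, splits and training.
#' @param n_subjects number of synthetic subjects (one scan each;
#'   default 48, giving about 40 training scans at the 8:2 split).
#' @param epochs_roi,epochs_align,epochs_landmark,epochs_baseline epoch
#'   budgets per stage (defaults 8/30/24/16: each stage's validation loss
#'   plateaus within its budget at this data scale).
#' @param factor_roi,factor_align,factor_landmark,factor_baseline offline
#'   augmentation factors per stage.
#' @param downsample_n training resolution (default 2048).
#' @param arms ablation arms to evaluate (default all five).
#' @param n_rotations_per_scan rotations drawn per test scan for the
#'   alignment evaluation (default 5).
#' @return A list with `models` (roinet, alignnet, landmarknet,
#'   baseline_net), `metrics` (named list of scalars), `ablation` (error
#'   tibble), `split`, `cfg` and per-stage `history`.
#' @export
pm_run_study <- function(seed = 1L, n_subjects = 48L,
                         epochs_roi = 8L, epochs_align = 30L,
                         epochs_landmark = 24L, epochs_baseline = 16L,
                         factor_roi = 3L, factor_align = 4L,
                         factor_landmark = 5L, factor_baseline = 3L,
                         downsample_n = 2048L,
                         arms = c("baseline", "crop+lm", "crop+align+lm",
                                  "roi+lm", "full"),
                         n_rotations_per_scan = 5L) {
  data <- pm_generate_dataset(n_subjects, visits = 1L,
                              repeats_per_visit = 2L, seed = pm_child_seed(seed, 1))
  data <- data[vapply(data, function(s) s$rep == 1L, logical(1))]
  sp <- pm_split_subjects(data, 0.8, seed = pm_child_seed(seed, 2))

  base_cfg <- function(epochs, factor) {
    pm_train_config(epochs = epochs, batch_size = 8L, preset = "tiny",
                    downsample_n = downsample_n,
                    augment_factor = factor,
                    seed = pm_child_seed(seed, 3))
  }
  cfg <- base_cfg(epochs_landmark, factor_landmark)

  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, t0) {
    message(sprintf("[study] %-9s %6.1f s", name, tic() - t0))
  }
  t0 <- tic()
  fit_roi <- pm_train_roinet(sp$train, base_cfg(epochs_roi, factor_roi))
  stage("roi", t0); t0 <- tic()
  fit_align <- pm_train_alignnet(sp$train,
                                 base_cfg(epochs_align, factor_align))
  stage("align", t0); t0 <- tic()
  lw <- pm_loss_weights(class_weights = "inverse_frequency", lambda_dist = 10)
  fit_lm <- pm_train_landmarknet(sp$train, cfg, lw)
  stage("landmark", t0); t0 <- tic()
  fit_base <- pm_train_landmarknet(sp$train,
                                   base_cfg(epochs_baseline, factor_baseline),
                                   lw, canonical = FALSE)
  stage("baseline", t0); t0 <- tic()
  models <- list(roinet = fit_roi$net, alignnet = fit_align$net,
                 landmarknet = fit_lm$net, baseline_net = fit_base$net)

  # (a) held-out ROI segmentation quality
  seg <- lapply(seq_along(sp$test), function(i) {
    sc <- sp$test[[i]]
    box <- pm_roi_box(sc$landmarks, cfg$roi_margin_mm)
    lab <- pm_label_in_box(sc$cloud, box)
    ds <- pm_downsample(sc$cloud, downsample_n,
                        seed = pm_child_seed(seed, 100 + i), labels = lab)
    dsc <- ds$cloud
    dsc$positions <- sweep(dsc$positions, 2, colMeans(dsc$positions))
    logp <- pm_segment_points(models$roinet, pm_point_features(dsc),
                              seed = pm_child_seed(seed, 200 + i))
    pred <- pm_labels(max.col(logp, ties.method = "first") - 1L, 2L, "roi")
    pm_iou_recall(pred, ds$labels)[2, ]
  })
  seg <- do.call(rbind, seg)

  # (b) rotation recovery on held-out canonical crops
  angle_errs <- unlist(lapply(seq_along(sp$test), function(i) {
    sc <- sp$test[[i]]
    can <- canonical_crop(sc, cfg, NULL, seed = pm_child_seed(seed, 300 + i))
    n <- min(downsample_n, pm_n_points(can$cloud))
    ds <- pm_downsample(can$cloud, n, seed = pm_child_seed(seed, 400 + i))
    ref <- sweep(ds$positions, 2, colMeans(ds$positions))
    vapply(seq_len(n_rotations_per_scan), function(j) {
      ang <- with_pm_seed(pm_child_seed(seed, 500 + i * 37 + j),
                          stats::runif(3, -20, 20)) * pi / 180
      R <- pm_rotation_from_euler(ang)
      Rhat <- pm_predict_rotation(models$alignnet,
                                  pm_point_features(pm_cloud(ref %*% t(R))),
                                  seed = pm_child_seed(seed, 600 + i))
      pm_rotation_angle(Rhat, t(R)) * 180 / pi
    }, numeric(1))
  }))

  # (c) held-out landmark-centre recovery on canonical crops
  lm_errs <- lapply(seq_along(sp$test), function(i) {
    sc <- sp$test[[i]]
    can <- canonical_crop(sc, cfg, NULL, seed = pm_child_seed(seed, 700 + i))
    n <- min(downsample_n, pm_n_points(can$cloud))
    ds <- pm_downsample(can$cloud, n, seed = pm_child_seed(seed, 800 + i))
    pred <- predict_landmarks_centered(ds, models$landmarknet,
                                       pm_child_seed(seed, 900 + i))
    err <- pm_localization_errors(pred, can$landmarks)
    err$subject_id <- sc$subject_id
    err
  })
  lm_errs <- do.call(rbind, lm_errs)

  stage("evals", t0); t0 <- tic()
  # (d) ablation arms on the raw held-out scans
  ablation <- pm_run_ablation(sp$test, models, arms, cfg,
                              seed = pm_child_seed(seed, 4))
  stage("ablation", t0)

  med <- function(x) stats::median(x, na.rm = TRUE)
  metrics <- list(
    roi_pelvic_iou = mean(seg$iou),
    roi_pelvic_recall = mean(seg$recall),
    align_median_angle_error_deg = med(angle_errs),
    landmark_median_center_error_mm = med(lm_errs$error_mm),
    landmark_mean_center_error_mm = mean(lm_errs$error_mm, na.rm = TRUE),
    landmark_missing = sum(lm_errs$missing),
    pipeline_median_error_mm =
      med(ablation$error_mm[ablation$arm == "full"]),
    baseline_median_error_mm =
      med(ablation$error_mm[ablation$arm == "baseline"]),
    n_train_scans = length(sp$train),
    n_test_scans = length(sp$test))
  list(models = models, metrics = metrics, ablation = ablation,
       landmark_errors = lm_errs, angle_errors = angle_errs,
       segmentation = seg, split = sp, cfg = cfg,
       history = list(roi = fit_roi$history, align = fit_align$history,
                      landmark = fit_lm$history, baseline = fit_base$history))
}
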
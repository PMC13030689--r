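#' Hard-label marker centres from per-point log-probabilities
#'
#' Each point takes its argmax class; the centre of marker class k
#' (1..6) is the coordinate mean of its points. A class with no points is
#' reported missing.
#'
#' @param log_probs N x 7 log-probabilities.
#' @param cloud the aligned `pm_cloud` (or N x 3 matrix) the probabilities
#'   refer to.
#' @return A `pm_landmarks` (missing classes as `NA`).
#' @export
pm_extract_marker_centers <- function(log_probs, cloud) {
  P <- if (inherits(cloud, "pm_cloud")) cloud$positions else as.matrix(cloud)
  if (nrow(P) != nrow(log_probs)) stop("log_probs and cloud must be aligned")
  if (ncol(log_probs) != 7L) stop("log_probs must have 7 classes")
  lab <- max.col(log_probs, ties.method = "first") - 1L
  out <- matrix(NA_real_, 6, 3, dimnames = list(pm_landmark_names(), NULL))
  for (k in 1:6) {
    rows <- which(lab == k)
    if (length(rows)) out[k, ] <- colMeans(P[rows, , drop = FALSE])
  }
  pm_landmarks(out)
}

#' Run the three-stage landmark localization pipeline on a raw scan
#'
#' Stage order: uniform downsampling, ROI segmentation, crop to the
#' predicted ROI points, centroid translation plus predicted rotation
#' correction, landmark-region labeling, hard-label centre extraction, and
#' inverse transformation of the centres back into the original scan
#' frame.
#'
#' @param raw_cloud a `pm_cloud` in the scanner frame.
#' @param roinet,alignnet,landmarknet trained networks (set `alignnet` to
#'   `NULL` to skip rotation correction).
#' @param cfg a `pm_train_config` (uses `downsample_n`, `min_roi_points`).
#' @param seed seed for downsampling and stage sampling.
#' @return A `pm_pipeline_result`: `landmarks` (scan frame), aligned-frame
#'   `landmarks_aligned`, `roi_mask` (labels on the downsampled cloud),
#'   `correction` (the applied `pm_transform`), `downsampled`/`roi_cloud`
#'   clouds, per-stage `timings` (seconds) and `provenance` (model config
#'   hashes and seeds).
#' @export
pm_run_pipeline <- function(raw_cloud, roinet, alignnet, landmarknet,
                            cfg = pm_train_config(), seed = 1L) {
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  n <- min(cfg$downsample_n, pm_n_points(raw_cloud))
  ds <- pm_downsample(raw_cloud, n, seed = pm_child_seed(seed, 1))
  ds <- pm_point_features(ds)
  timings["downsample"] <- tic() - t0

  t0 <- tic()
  # the networks are trained on centroid-translated clouds; segment in that frame
  ds_c <- ds
  ds_c$positions <- sweep(ds$positions, 2, colMeans(ds$positions))
  logp_roi <- pm_segment_points(roinet, pm_point_features(ds_c),
                                seed = pm_child_seed(seed, 2))
  mask <- pm_labels(max.col(logp_roi, ties.method = "first") - 1L, 2L, "roi")
  keep <- which(as.integer(mask) == 1L)
  timings["roi"] <- tic() - t0
  min_pts <- cfg$min_roi_points
  if (is.null(min_pts)) {
    deepest <- landmarknet$config$sa[[length(landmarknet$config$sa)]]$npoint
    min_pts <- max(deepest, 64L)
  }
  if (length(keep) < min_pts) {
    cond <- structure(class = c("pm_roi_failure", "error", "condition"),
                      list(message = sprintf(
                        "predicted ROI too small: %d points (minimum %d)",
                        length(keep), min_pts),
                        call = sys.call(), mask = mask, cloud = ds))
    stop(cond)
  }
  roi_cloud <- pm_cloud_subset(ds, keep)

  t0 <- tic()
  ctr <- colMeans(roi_cloud$positions)
  centered <- roi_cloud
  centered$positions <- sweep(centered$positions, 2, ctr)
  if (!is.null(alignnet)) {
    R <- pm_predict_rotation(alignnet, pm_point_features(centered),
                             seed = pm_child_seed(seed, 3))
  } else {
    R <- diag(3)
  }
  correction <- pm_transform(R, -as.numeric(R %*% ctr))
  aligned <- pm_apply_transform(roi_cloud, correction)
  timings["align"] <- tic() - t0

  t0 <- tic()
  logp_lm <- pm_segment_points(landmarknet, pm_point_features(aligned),
                               seed = pm_child_seed(seed, 4))
  centers_aligned <- pm_extract_marker_centers(logp_lm, aligned)
  centers_scan <- pm_apply_transform(centers_aligned,
                                     pm_transform_inverse(correction))
  timings["landmark"] <- tic() - t0

  structure(list(landmarks = centers_scan,
                 landmarks_aligned = centers_aligned,
                 roi_mask = mask,
                 correction = correction,
                 downsampled = ds,
                 roi_cloud = roi_cloud,
                 timings = timings,
                 provenance = list(
                   roinet = pm_config_hash(roinet$config),
                   alignnet = if (is.null(alignnet)) NA_character_ else
                     pm_config_hash(alignnet$config),
                   landmarknet = pm_config_hash(landmarknet$config),
                   seed = seed)),
            class = "pm_pipeline_result")
}

#' @export
print.pm_pipeline_result <- function(x, ...) {
  cat("<pm_pipeline_result>\n")
  cat(sprintf("  ROI points kept: %d / %d\n", pm_n_points(x$roi_cloud),
              pm_n_points(x$downsampled)))
  cat(sprintf("  landmarks found: %d / 6\n", sum(pm_landmarks_present(x$landmarks))))
  cat(sprintf("  total time: %.2f s\n", sum(x$timings)))
  invisible(x)
}

arm_names <- function() c("baseline", "crop+lm", "crop+align+lm", "roi+lm", "full")

predict_landmarks_centered <- function(cloud, net, seed) {
  ctr <- colMeans(cloud$positions)
  centered <- cloud
  centered$positions <- sweep(centered$positions, 2, ctr)
  logp <- pm_segment_points(net, pm_point_features(centered), seed = seed)
  centers <- pm_extract_marker_centers(logp, centered)
  pm_apply_transform(centers, pm_transform(diag(3), ctr))
}

#' Run one ablation configuration over a set of scans
#'
#' The five arms mirror the evaluation protocol: (1) `baseline` -- the
#' landmark network applied directly to the raw downsampled cloud;
#' (2) `crop+lm` -- randomized manual crop then the landmark network;
#' (3) `crop+align+lm` -- manual crop, rotation correction, landmark
#' network; (4) `roi+lm` -- learned ROI crop then the landmark network;
#' (5) `full` -- the fully integrated pipeline.
#'
#' @param name one of `"baseline"`, `"crop+lm"`, `"crop+align+lm"`,
#'   `"roi+lm"`, `"full"`.
#' @param scans test scan records (with ground-truth landmarks).
#' @param models list with `roinet`, `alignnet`, `landmarknet` and
#'   `baseline_net` (the landmark network trained on raw clouds, used by
#'   the baseline arm).
#' @param cfg a `pm_train_config`.
#' @param seed evaluation seed (manual-crop draws, sampling).
#' @return A tibble with one row per scan and landmark: `arm`, `scan_id`,
#'   `subject_id`, `landmark`, `error_mm` (`NA` when the prediction is
#'   missing), `missing`.
#' @export
pm_run_configuration <- function(name, scans, models,
                                 cfg = pm_train_config(), seed = 1L) {
  name <- match.arg(name, arm_names())
  rows <- list()
  for (i in seq_along(scans)) {
    sc <- scans[[i]]
    pred <- switch(
      name,
      "baseline" = {
        n <- min(cfg$downsample_n, pm_n_points(sc$cloud))
        ds <- pm_downsample(sc$cloud, n, seed = pm_child_seed(seed, i))
        predict_landmarks_centered(ds, models$baseline_net,
                                   pm_child_seed(seed, 1000 + i))
      },
      "crop+lm" = {
        cr <- pm_simulate_manual_crop(sc$cloud, sc$landmarks,
                                      seed = pm_child_seed(seed, 2000 + i))
        n <- min(cfg$downsample_n, pm_n_points(cr$cloud))
        ds <- pm_downsample(cr$cloud, n, seed = pm_child_seed(seed, i))
        predict_landmarks_centered(ds, models$landmarknet,
                                   pm_child_seed(seed, 1000 + i))
      },
      "crop+align+lm" = {
        cr <- pm_simulate_manual_crop(sc$cloud, sc$landmarks,
                                      seed = pm_child_seed(seed, 2000 + i))
        n <- min(cfg$downsample_n, pm_n_points(cr$cloud))
        ds <- pm_downsample(cr$cloud, n, seed = pm_child_seed(seed, i))
        ctr <- colMeans(ds$positions)
        centered <- ds
        centered$positions <- sweep(centered$positions, 2, ctr)
        R <- pm_predict_rotation(models$alignnet, pm_point_features(centered),
                                 seed = pm_child_seed(seed, 3000 + i))
        correction <- pm_transform(R, -as.numeric(R %*% ctr))
        aligned <- pm_apply_transform(ds, correction)
        centers <- predict_landmarks_centered(aligned, models$landmarknet,
                                              pm_child_seed(seed, 1000 + i))
        pm_apply_transform(centers, pm_transform_inverse(correction))
      },
      "roi+lm" = {
        res <- pm_run_pipeline(sc$cloud, models$roinet, NULL,
                               models$landmarknet, cfg,
                               seed = pm_child_seed(seed, 4000 + i))
        res$landmarks
      },
      "full" = {
        res <- pm_run_pipeline(sc$cloud, models$roinet, models$alignnet,
                               models$landmarknet, cfg,
                               seed = pm_child_seed(seed, 4000 + i))
        res$landmarks
      })
    err <- pm_localization_errors(pred, sc$landmarks)
    err$arm <- name
    err$scan_id <- sc$scan_id
    err$subject_id <- sc$subject_id
    rows[[i]] <- err
  }
  out <- do.call(rbind, rows)
  out[, c("arm", "scan_id", "subject_id", "landmark", "error_mm", "missing")]
}

#' Run several ablation arms and bind the error tables
#'
#' @param arms character vector of arm names (default all five).
#' @inheritParams pm_run_configuration
#' @return Combined tibble of per-scan, per-landmark errors.
#' @export
pm_run_ablation <- function(scans, models, arms = arm_names(),
                            cfg = pm_train_config(), seed = 1L) {
  do.call(rbind, lapply(arms, function(a) {
    pm_run_configuration(a, scans, models, cfg, seed)
  }))
}
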
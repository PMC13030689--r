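#' Training configuration
#'
#' Defaults follow the study protocol: 20 epochs, Adam with batch size 32,
#' 8:2 subject-level split, 16,384-point downsampling, twentyfold
#' augmentation with +/-20 degree rotations. The `"tiny"` preset plus
#' reduced `downsample_n`/`augment_factor` runs the same experiments at
#' desk scale.
#'
#' @param epochs training epochs (default 20).
#' @param batch_size gradient-accumulation batch size (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed master seed for weight init, shuffling, sampling, dropout.
#' @param val_split fraction of subjects used for training within the
#'   provided data; the rest validate model selection (default 0.8).
#' @param preset `"full"` or `"tiny"` model preset.
#' @param downsample_n points per cloud after uniform downsampling.
#' @param augment_factor augmented samples per input cloud.
#' @param augment_range_deg per-axis augmentation rotation half-range.
#' @param radius_mm landmark-region labeling radius (default 10).
#' @param roi_margin_mm ROI box margin (default 100).
#' @param weight_decay decoupled weight decay on linear weights
#'   (default 1e-4).
#' @param min_roi_points minimum predicted-ROI size accepted at inference;
#'   defaults to the deepest stage size of the preset.
#' @return A `pm_train_config` list.
#' @export
pm_train_config <- function(epochs = 20L, batch_size = 32L, lr = 1e-3,
                            seed = 1L, val_split = 0.8,
                            preset = c("full", "tiny"),
                            downsample_n = 16384L, augment_factor = 20L,
                            augment_range_deg = 20, radius_mm = 10,
                            roi_margin_mm = 100, min_roi_points = NULL,
                            weight_decay = 1e-4) {
  preset <- match.arg(preset)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (val_split <= 0 || val_split >= 1) stop("val_split must be in (0, 1)")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, seed = as.integer(seed), val_split = val_split,
                 preset = preset, downsample_n = as.integer(downsample_n),
                 augment_factor = as.integer(augment_factor),
                 augment_range_deg = augment_range_deg, radius_mm = radius_mm,
                 roi_margin_mm = roi_margin_mm,
                 min_roi_points = min_roi_points,
                 weight_decay = weight_decay),
            class = "pm_train_config")
}

#' Subject-level train/test split
#'
#' All scans of a subject land on exactly one side, preventing
#' subject-level leakage between training and testing.
#'
#' @param dataset list of scan records carrying `subject_id` (e.g. from
#'   [pm_generate_dataset()]).
#' @param ratio fraction of subjects assigned to the training side
#'   (default 0.8).
#' @param seed split seed.
#' @return `list(train = ..., test = ...)` of scan records.
#' @export
pm_split_subjects <- function(dataset, ratio = 0.8, seed = 1L) {
  subj <- vapply(dataset, function(s) s$subject_id, character(1))
  u <- unique(subj)
  if (length(u) < 2L) stop("need at least 2 subjects to split")
  n_test <- max(1L, round((1 - ratio) * length(u)))
  n_test <- min(n_test, length(u) - 1L)
  test_subj <- with_pm_seed(seed, sample(u, n_test))
  list(train = dataset[!subj %in% test_subj],
       test = dataset[subj %in% test_subj])
}

# ---- sample builders ----------------------------------------------------

new_sample <- function(cloud, subject_id, labels = NULL, landmarks = NULL,
                       ref = NULL, R_target = NULL) {
  e <- new.env(parent = emptyenv())  # per-sample graph cache
  list(cloud = pm_point_features(cloud), labels = labels,
       landmarks = landmarks, ref = ref, R_target = R_target,
       subject_id = subject_id, genv = e)
}

sample_graph <- function(net, sample, seed) {
  key <- paste0("g", net$kind, pm_config_hash(net$config))
  g <- sample$genv[[key]]
  if (is.null(g)) {
    g <- pm_build_graph(sample$cloud$positions, net$config, seed)
    sample$genv[[key]] <- g
  }
  g
}

#' Build ROI-segmentation training samples from scans
#'
#' Per scan: binary in-box labels from the landmark ROI box, uniform
#' downsampling, then offline centroid-translate + random-rotation
#' augmentation; features are rebuilt per augmented sample.
#'
#' @param scans scan records (cloud + landmarks + subject_id).
#' @param cfg a `pm_train_config`.
#' @return List of training samples.
#' @export
pm_build_roi_samples <- function(scans, cfg) {
  out <- list()
  for (i in seq_along(scans)) {
    sc <- scans[[i]]
    box <- pm_roi_box(sc$landmarks, cfg$roi_margin_mm)
    lab <- pm_label_in_box(sc$cloud, box)
    # each augmented copy draws its own point subset, so the offline factor
    # multiplies label diversity as well as pose diversity
    for (s in seq_len(cfg$augment_factor)) {
      ds <- pm_downsample(sc$cloud, cfg$downsample_n,
                          seed = pm_child_seed(cfg$seed, 20000 + 100 * i + s),
                          labels = lab)
      a <- pm_augment(ds$cloud, labels = ds$labels,
                      cfg = pm_augment_config(cfg$augment_range_deg, 1L,
                                              cfg$downsample_n,
                                              pm_child_seed(cfg$seed, 40000 + 100 * i + s)))[[1]]
      out[[length(out) + 1L]] <- new_sample(a$cloud, sc$subject_id,
                                            labels = a$labels)
    }
  }
  out
}

crop_roi <- function(scan, cfg, roinet = NULL, seed = 1L) {
  if (is.null(roinet)) {
    box <- pm_roi_box(scan$landmarks, cfg$roi_margin_mm)
    keep <- which(as.integer(pm_label_in_box(scan$cloud, box)) == 1L)
    return(pm_cloud_subset(scan$cloud, keep))
  }
  ds <- pm_downsample(scan$cloud, cfg$downsample_n, seed = seed)
  ds_c <- ds
  ds_c$positions <- sweep(ds$positions, 2, colMeans(ds$positions))
  logp <- pm_segment_points(roinet, pm_point_features(ds_c), seed = seed)
  keep <- which(max.col(logp, ties.method = "first") == 2L)
  pm_cloud_subset(ds, keep)
}

canonical_crop <- function(scan, cfg, roinet = NULL, seed = 1L) {
  crop <- crop_roi(scan, cfg, roinet, seed)
  tf <- pm_canonicalize_pose(scan$landmarks)
  list(cloud = pm_apply_transform(crop, tf),
       landmarks = pm_apply_transform(scan$landmarks, tf))
}

#' Build alignment training samples from scans
#'
#' Per scan: ROI crop (predicted by `roinet` when given, otherwise the
#' ground-truth landmark box), canonicalization from ground-truth
#' landmarks, downsampling, centroid centering (the reference cloud), then
#' augmentation rotations whose inverses are the regression targets.
#'
#' @param scans scan records.
#' @param cfg a `pm_train_config`.
#' @param roinet optional trained ROI network used to produce the crops.
#' @return List of training samples (cloud, `ref` positions, `R_target`).
#' @export
pm_build_align_samples <- function(scans, cfg, roinet = NULL) {
  out <- list()
  for (i in seq_along(scans)) {
    sc <- scans[[i]]
    can <- canonical_crop(sc, cfg, roinet, seed = pm_child_seed(cfg$seed, 60 + i))
    n <- min(cfg$downsample_n, pm_n_points(can$cloud))
    for (s in seq_len(cfg$augment_factor)) {
      ds <- pm_downsample(can$cloud, n,
                          seed = pm_child_seed(cfg$seed, 60000 + 100 * i + s))
      ref <- sweep(ds$positions, 2, colMeans(ds$positions))
      a <- pm_augment(pm_cloud(ref, subject_id = sc$subject_id),
                      cfg = pm_augment_config(cfg$augment_range_deg, 1L, n,
                                              pm_child_seed(cfg$seed, 80000 + 100 * i + s)))[[1]]
      out[[length(out) + 1L]] <- new_sample(a$cloud, sc$subject_id,
                                            ref = ref, R_target = a$correction)
    }
  }
  out
}

#' Build landmark-labeling training samples from scans
#'
#' Per scan: canonical ROI crop, 10 mm landmark-region labels assigned on
#' the full-resolution crop, downsampling with consistent label subsetting,
#' then augmentation (labels carried, landmark coordinates transformed
#' identically).
#'
#' @param scans scan records.
#' @param cfg a `pm_train_config`.
#' @param roinet optional trained ROI network for predicted crops.
#' @param canonical if `FALSE`, skip canonicalization and crop (baseline
#'   arm: the landmark network sees the raw downsampled cloud).
#' @return List of training samples (cloud, labels, landmarks).
#' @export
pm_build_landmark_samples <- function(scans, cfg, roinet = NULL,
                                      canonical = TRUE) {
  out <- list()
  for (i in seq_along(scans)) {
    sc <- scans[[i]]
    if (canonical) {
      can <- canonical_crop(sc, cfg, roinet, seed = pm_child_seed(cfg$seed, 120 + i))
      cloud <- can$cloud; lm <- can$landmarks
    } else {
      cloud <- sc$cloud; lm <- sc$landmarks
    }
    lab <- pm_label_landmark_regions(cloud, lm, cfg$radius_mm)
    n <- min(cfg$downsample_n, pm_n_points(cloud))
    for (s in seq_len(cfg$augment_factor)) {
      ds <- pm_downsample(cloud, n,
                          seed = pm_child_seed(cfg$seed, 140000 + 100 * i + s),
                          labels = lab)
      a <- pm_augment(ds$cloud, labels = ds$labels, landmarks = lm,
                      cfg = pm_augment_config(cfg$augment_range_deg, 1L, n,
                                              pm_child_seed(cfg$seed, 160000 + 100 * i + s)))[[1]]
      out[[length(out) + 1L]] <- new_sample(a$cloud, sc$subject_id,
                                            labels = a$labels,
                                            landmarks = a$landmarks)
    }
  }
  out
}

# ---- generic training loops --------------------------------------------

# step decay: halve the learning rate at 60% and 85% of the epoch budget
lr_decay <- function(ep, total) {
  if (ep > 0.85 * total) 0.25 else if (ep > 0.6 * total) 0.5 else 1
}

split_samples_by_subject <- function(samples, val_split, seed) {
  subj <- vapply(samples, function(s) s$subject_id, character(1))
  u <- unique(subj)
  if (length(u) < 2L) {
    # too few subjects for a held-out validation: validate on training data
    return(list(train = samples, val = samples))
  }
  n_val <- max(1L, round((1 - val_split) * length(u)))
  n_val <- min(n_val, length(u) - 1L)
  val_subj <- with_pm_seed(seed, sample(u, n_val))
  list(train = samples[!subj %in% val_subj], val = samples[subj %in% val_subj])
}

seg_sample_loss <- function(net, sample, train, weights, use_dist, cw,
                            seed, dropout_seed) {
  g <- sample_graph(net, sample, seed)
  fwd <- pm_seg_forward(net, sample$cloud$features, g, train = train,
                        dropout_seed = dropout_seed)
  nll <- nll_with_grad(fwd$logp, sample$labels, cw)
  loss <- nll$loss
  dlogp <- nll$dlogp
  dist <- NA_real_
  if (use_dist) {
    sc <- soft_center_loss_grad(fwd$logp, sample$cloud$positions,
                                sample$landmarks)
    loss <- loss + weights$lambda_dist * sc$loss
    dlogp <- dlogp + weights$lambda_dist * sc$dlogp
    dist <- sc$loss
  }
  list(loss = loss, nll = nll$loss, dist = dist, dlogp = dlogp, fwd = fwd)
}

train_seg_generic <- function(samples, n_classes, cfg, weights, use_dist) {
  sp <- split_samples_by_subject(samples, cfg$val_split,
                                 pm_child_seed(cfg$seed, 7))
  net <- pm_seg_net(pm_seg_config(cfg$preset, n_classes), seed = cfg$seed)
  nn_adam_init(net, lr = cfg$lr, weight_decay = cfg$weight_decay %||% 0)
  cw <- weights$class_weights
  if (identical(cw, "inverse_frequency")) {
    all_lab <- unlist(lapply(sp$train, function(s) as.integer(s$labels)))
    cw <- resolve_class_weights("inverse_frequency", all_lab, n_classes,
                                weights$class_weight_exponent %||% 1)
  }
  history <- list()
  best <- list(loss = Inf, state = NULL)
  step <- 0L
  # the distance term joins after a label-only warm-up quarter: per-class
  # regions must exist before their soft centres carry a useful gradient
  warmup <- if (use_dist) floor(0.25 * cfg$epochs) else 0L
  for (ep in seq_len(cfg$epochs)) {
    net$adam$lr <- cfg$lr * lr_decay(ep, cfg$epochs)
    dist_now <- use_dist && ep > warmup
    ord <- with_pm_seed(pm_child_seed(cfg$seed, 500 + ep),
                        sample(seq_along(sp$train)))
    ep_loss <- 0
    for (b0 in seq(1L, length(ord), by = cfg$batch_size)) {
      batch <- ord[b0:min(length(ord), b0 + cfg$batch_size - 1L)]
      nn_zero_grad(net)
      for (i in batch) {
        step <- step + 1L
        r <- seg_sample_loss(net, sp$train[[i]], TRUE, weights, dist_now, cw,
                             seed = pm_child_seed(cfg$seed, 3),
                             dropout_seed = pm_child_seed(cfg$seed, 9000 + step))
        if (!is.finite(r$loss)) stop("non-finite training loss at step ", step)
        ep_loss <- ep_loss + r$loss
        pm_seg_backward(net, r$fwd$cache, r$dlogp)
      }
      nn_adam_step(net, scale = 1 / length(batch))
    }
    val <- t(vapply(sp$val, function(s) {
      r <- seg_sample_loss(net, s, FALSE, weights, use_dist, cw,
                           seed = pm_child_seed(cfg$seed, 3), dropout_seed = 1L)
      c(r$loss, r$nll, r$dist)
    }, numeric(3)))
    vl <- mean(val[, 1])
    history[[ep]] <- tibble::tibble(epoch = ep,
                                    train_loss = ep_loss / length(ord),
                                    val_loss = vl,
                                    val_nll = mean(val[, 2]),
                                    val_dist_mm = mean(val[, 3]))
    if (vl < best$loss) best <- list(loss = vl, state = nn_state(net), epoch = ep)
  }
  nn_restore(net, best$state)
  list(net = net, history = do.call(rbind, history), best_epoch = best$epoch)
}

#' Train the ROI segmentation network
#'
#' Negative log-likelihood objective over binary in-box labels; the
#' checkpoint with the lowest validation loss (subject-level validation
#' split) is returned.
#'
#' @param scans training scan records.
#' @param cfg a `pm_train_config`.
#' @param weights a `pm_loss_weights` (class weights only).
#' @return `list(net, history, best_epoch)`.
#' @export
pm_train_roinet <- function(scans, cfg = pm_train_config(),
                            weights = pm_loss_weights()) {
  samples <- pm_build_roi_samples(scans, cfg)
  train_seg_generic(samples, 2L, cfg, weights, use_dist = FALSE)
}

#' Train the landmark-labeling network
#'
#' Objective: NLL over 10 mm landmark-region labels plus
#' `lambda_dist` times the soft-centre distance to the ground-truth marker
#' coordinates.
#'
#' @param scans training scan records.
#' @param cfg a `pm_train_config`.
#' @param weights a `pm_loss_weights`.
#' @param roinet optional ROI network for predicted crops.
#' @param canonical train on canonicalized ROI crops (`TRUE`, pipeline
#'   stage) or raw downsampled clouds (`FALSE`, baseline arm).
#' @return `list(net, history, best_epoch)`.
#' @export
pm_train_landmarknet <- function(scans, cfg = pm_train_config(),
                                 weights = pm_loss_weights(),
                                 roinet = NULL, canonical = TRUE) {
  samples <- pm_build_landmark_samples(scans, cfg, roinet, canonical)
  train_seg_generic(samples, 7L, cfg, weights, use_dist = TRUE)
}

#' Train the alignment (rotation-regression) network
#'
#' Objective: mean point-set distance after applying the predicted
#' rotation, plus the orthonormality regularizer on the raw 3 x 3 output
#' and the Euler-angle distance to the reference rotation.
#'
#' @param scans training scan records.
#' @param cfg a `pm_train_config`.
#' @param weights a `pm_loss_weights` (`lambda_rot`, `lambda_euler`).
#' @param roinet optional ROI network; when given, training inputs are the
#'   crops it predicts (the literal pipeline composition), otherwise the
#'   ground-truth landmark-box crops.
#' @return `list(net, history, best_epoch)`.
#' @export
pm_train_alignnet <- function(scans, cfg = pm_train_config(),
                              weights = pm_loss_weights(), roinet = NULL) {
  samples <- pm_build_align_samples(scans, cfg, roinet)
  sp <- split_samples_by_subject(samples, cfg$val_split,
                                 pm_child_seed(cfg$seed, 7))
  net <- pm_align_net(pm_align_config(cfg$preset), seed = cfg$seed)
  nn_adam_init(net, lr = cfg$lr, weight_decay = cfg$weight_decay %||% 0)
  history <- list()
  best <- list(loss = Inf, state = NULL)
  align_loss <- function(sample, train) {
    g <- sample_graph(net, sample, pm_child_seed(cfg$seed, 3))
    fwd <- pm_align_forward(net, sample$cloud$features, g, train = train)
    Q <- sample$cloud$positions
    U <- Q %*% t(fwd$R) - sample$ref
    nu <- sqrt(rowSums(U^2))
    pts <- mean(nu)
    rr <- rotation_reg_grad(fwd$M)
    eul <- pm_euler_angle_loss(fwd$R, sample$R_target)
    total <- pts + weights$lambda_rot * rr$loss + weights$lambda_euler * eul
    list(total = total, pts = pts, rot = rr$loss, euler = eul,
         fwd = fwd, U = U, nu = nu, Q = Q, rr = rr)
  }
  for (ep in seq_len(cfg$epochs)) {
    net$adam$lr <- cfg$lr * lr_decay(ep, cfg$epochs)
    ord <- with_pm_seed(pm_child_seed(cfg$seed, 500 + ep),
                        sample(seq_along(sp$train)))
    ep_loss <- 0
    for (b0 in seq(1L, length(ord), by = cfg$batch_size)) {
      batch <- ord[b0:min(length(ord), b0 + cfg$batch_size - 1L)]
      nn_zero_grad(net)
      for (i in batch) {
        s <- sp$train[[i]]
        r <- align_loss(s, TRUE)
        if (!is.finite(r$total)) stop("non-finite alignment loss")
        ep_loss <- ep_loss + r$total
        Un <- r$U / pmax(r$nu, 1e-12)
        dR <- crossprod(Un, r$Q) / nrow(r$Q)
        if (weights$lambda_euler > 0) {
          dR <- dR + weights$lambda_euler * euler_loss_grad_fd(r$fwd$R, s$R_target)
        }
        dM <- svd_project_bwd(r$fwd$M, dR) + weights$lambda_rot * r$rr$dR
        pm_align_backward(net, r$fwd$cache, dM)
      }
      nn_adam_step(net, scale = 1 / length(batch))
    }
    val_parts <- t(vapply(sp$val, function(s) {
      r <- align_loss(s, FALSE); c(r$total, r$pts, r$euler)
    }, numeric(3)))
    vl <- mean(val_parts[, 1])
    history[[ep]] <- tibble::tibble(epoch = ep,
                                    train_loss = ep_loss / length(ord),
                                    val_loss = vl,
                                    val_pts_mm = mean(val_parts[, 2]),
                                    val_euler_rad = mean(val_parts[, 3]))
    if (vl < best$loss) best <- list(loss = vl, state = nn_state(net), epoch = ep)
  }
  nn_restore(net, best$state)
  list(net = net, history = do.call(rbind, history), best_epoch = best$epoch)
}
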
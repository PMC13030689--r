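#' Axis-aligned ROI box
#'
#' @param bounds 3 x 2 matrix (rows x/y/z, columns min/max) in mm.
#' @return An object of class `pm_box`.
#' @export
pm_box <- function(bounds) {
  bounds <- as.matrix(bounds)
  if (!all(dim(bounds) == c(3L, 2L))) stop("bounds must be 3 x 2 (axis x min/max)")
  if (any(bounds[, 1] >= bounds[, 2])) stop("each axis must have min < max")
  dimnames(bounds) <- list(c("x", "y", "z"), c("min", "max"))
  structure(bounds, class = c("pm_box", "matrix", "array"))
}

#' Posterior pelvic ROI box from landmarks
#'
#' The ROI is the landmarks' axis-aligned bounding box expanded by a fixed
#' margin on every side: per axis, `(min - margin, max + margin)`. The
#' default 100 mm margin captures the posterior pelvic surface around the
#' six markers.
#'
#' @param landmarks a `pm_landmarks` with at least one landmark present.
#' @param margin_mm margin in mm (default 100).
#' @return A `pm_box`.
#' @export
pm_roi_box <- function(landmarks, margin_mm = 100) {
  m <- unclass(landmarks)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (!nrow(m)) stop("landmark set is empty")
  lo <- apply(m, 2, min) - margin_mm
  hi <- apply(m, 2, max) + margin_mm
  pm_box(cbind(lo, hi))
}

#' Binary in-box labels for a point cloud
#'
#' Points inside the ROI box get label 1, points outside get 0. The box is
#' closed: a point exactly on a bound counts as inside.
#'
#' @param cloud a `pm_cloud`.
#' @param box a `pm_box`.
#' @return A `pm_labels` with semantics `"roi"` (C = 2).
#' @export
pm_label_in_box <- function(cloud, box) {
  P <- cloud$positions
  inside <- P[, 1] >= box[1, 1] & P[, 1] <= box[1, 2] &
    P[, 2] >= box[2, 1] & P[, 2] <= box[2, 2] &
    P[, 3] >= box[3, 1] & P[, 3] <= box[3, 2]
  pm_labels(as.integer(inside), 2L, "roi")
}

#' Landmark-region labels for a point cloud
#'
#' Every point within `radius_mm` of a landmark centre inherits that
#' landmark's class (1..6 in canonical order); all other points are
#' background (0). The sphere test is closed (distance <= radius counts as
#' inside). A point within radius of several landmarks takes the nearest
#' one's class.
#'
#' @param cloud a `pm_cloud`.
#' @param landmarks a `pm_landmarks` with at least one landmark present.
#' @param radius_mm labeling radius in mm (default 10, the marker-region
#'   radius used for training).
#' @return A `pm_labels` with semantics `"landmark"` (C = 7).
#' @export
pm_label_landmark_regions <- function(cloud, landmarks, radius_mm = 10) {
  if (radius_mm <= 0) stop("radius_mm must be positive")
  m <- unclass(landmarks)
  present <- which(stats::complete.cases(m))
  if (!length(present)) stop("landmark set is empty")
  P <- cloud$positions
  n <- nrow(P)
  best_d2 <- rep(Inf, n)
  lab <- integer(n)
  r2 <- radius_mm^2
  for (k in present) {
    d2 <- (P[, 1] - m[k, 1])^2 + (P[, 2] - m[k, 2])^2 + (P[, 3] - m[k, 3])^2
    hit <- d2 <= r2 & d2 < best_d2
    lab[hit] <- k
    best_d2[hit] <- d2[hit]
  }
  pm_labels(lab, 7L, "landmark")
}

#' Uniform random downsampling without replacement
#'
#' @param cloud a `pm_cloud` with at least `n` points.
#' @param n target point count (default 16384, the training resolution).
#' @param seed integer seed; the selected index set is a pure function of
#'   `(cloud size, n, seed)`.
#' @param labels optional `pm_labels` to subset consistently.
#' @return The downsampled `pm_cloud`; if `labels` is given, a list
#'   `list(cloud, labels, idx)`.
#' @export
pm_downsample <- function(cloud, n = 16384L, seed = 1L, labels = NULL) {
  N <- pm_n_points(cloud)
  if (N < n) stop(sprintf("insufficient points: cloud has %d, need %d (sampling is without replacement)", N, n))
  idx <- with_pm_seed(seed, sample.int(N, n, replace = FALSE))
  out <- pm_cloud_subset(cloud, idx)
  if (is.null(labels)) return(out)
  list(cloud = out, labels = labels[idx], idx = idx)
}

#' Per-point input features: raw and bounding-box-normalized coordinates
#'
#' Channels 1-3 are the raw (x, y, z) coordinates in mm; channels 4-6 are
#' the coordinates min-max normalized to [0, 1] over the cloud's own
#' axis-aligned bounding box. An axis with zero extent normalizes to 0.5.
#' Together with the raw coordinates consumed separately for neighbourhood
#' distance computation, the first set-abstraction layer therefore sees 9
#' channels.
#'
#' @param cloud a `pm_cloud`.
#' @return The `pm_cloud` with a 6-column feature matrix
#'   (`x, y, z, nx, ny, nz`).
#' @export
pm_point_features <- function(cloud) {
  P <- cloud$positions
  lo <- apply(P, 2, min)
  hi <- apply(P, 2, max)
  ext <- hi - lo
  Nm <- matrix(0.5, nrow(P), 3)
  for (j in 1:3) {
    if (ext[j] > 0) Nm[, j] <- (P[, j] - lo[j]) / ext[j]
  }
  F <- cbind(P, Nm)
  colnames(F) <- c("x", "y", "z", "nx", "ny", "nz")
  cloud$features <- F
  cloud
}

#' Augmentation configuration
#'
#' Offline augmentation translates each cloud to its centroid and applies a
#' random rotation with independent per-axis angles uniform in
#' `[-range, +range]` degrees (intrinsic x-y-z composition), yielding
#' `factor` samples per input.
#'
#' @param rotation_range_deg per-axis rotation half-range in degrees
#'   (default 20).
#' @param factor number of augmented samples per input (default 20).
#' @param downsample_n downsample target used by dataset builders
#'   (default 16384).
#' @param seed master seed; per-sample child seeds are derived by counter.
#' @return An object of class `pm_augment_config`.
#' @export
pm_augment_config <- function(rotation_range_deg = 20, factor = 20L,
                              downsample_n = 16384L, seed = 1L) {
  if (factor < 1L) stop("factor must be >= 1")
  if (downsample_n < 1L) stop("downsample_n must be >= 1")
  if (rotation_range_deg < 0) stop("rotation range must be >= 0")
  structure(list(rotation_range_deg = rotation_range_deg,
                 factor = as.integer(factor),
                 downsample_n = as.integer(downsample_n),
                 seed = as.integer(seed)),
            class = "pm_augment_config")
}

# deterministic child-seed stream: one master seed, counter-derived children
pm_child_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 7919 + 11) %% 2147483587)
}

with_pm_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Centroid-translate + random-rotation augmentation
#'
#' Each augmented sample is the input cloud translated to its centroid and
#' rotated by independent per-axis angles drawn uniformly from
#' `[-range, +range]` degrees. Labels are carried unchanged; landmark
#' coordinates are transformed identically; the applied rotation (the
#' regression target of the alignment network) and its inverse (the
#' correction) are recorded with each sample.
#'
#' @param cloud a `pm_cloud`.
#' @param labels optional `pm_labels` carried to every sample.
#' @param landmarks optional `pm_landmarks` transformed with the cloud.
#' @param cfg a `pm_augment_config`.
#' @return A list of `cfg$factor` samples, each a list with elements
#'   `cloud`, `labels`, `landmarks`, `rotation` (applied), `correction`
#'   (its inverse), `angles_deg`, and `centroid` (of the input cloud, mm).
#' @export
pm_augment <- function(cloud, labels = NULL, landmarks = NULL, cfg = pm_augment_config()) {
  ctr <- colMeans(cloud$positions)
  rng <- cfg$rotation_range_deg * pi / 180
  out <- vector("list", cfg$factor)
  for (s in seq_len(cfg$factor)) {
    ang <- with_pm_seed(pm_child_seed(cfg$seed, s), stats::runif(3, -rng, rng))
    R <- pm_rotation_from_euler(ang)
    tf <- pm_transform(R, -as.numeric(R %*% ctr))
    lm_s <- if (is.null(landmarks)) NULL else pm_apply_transform(landmarks, tf)
    out[[s]] <- list(cloud = pm_apply_transform(cloud, tf),
                     labels = labels,
                     landmarks = lm_s,
                     rotation = R,
                     correction = t(R),
                     angles_deg = ang * 180 / pi,
                     centroid = ctr)
  }
  out
}

#' Randomized manual-crop simulation
#'
#' Emulates clinician-guided visual ROI selection: the fixed 100 mm margin
#' of the ROI box is replaced by six independent offsets drawn uniformly
#' from `[lo, hi]` mm, one per lower and upper bound along each axis.
#'
#' @param cloud a `pm_cloud`.
#' @param landmarks a `pm_landmarks` (at least one present).
#' @param lo,hi offset range in mm (defaults 50 and 150).
#' @param seed integer seed; the box is deterministic per seed.
#' @return A list with `cloud` (points inside the crop), `box` (the
#'   `pm_box`), `offsets` (3 x 2 matrix of drawn offsets) and `idx` (kept
#'   indices in the input cloud).
#' @export
pm_simulate_manual_crop <- function(cloud, landmarks, lo = 50, hi = 150, seed = 1L) {
  m <- unclass(landmarks)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (!nrow(m)) stop("landmark set is empty")
  off <- with_pm_seed(seed, matrix(stats::runif(6, lo, hi), 3, 2))
  bounds <- cbind(apply(m, 2, min) - off[, 1], apply(m, 2, max) + off[, 2])
  box <- pm_box(bounds)
  keep <- which(as.integer(pm_label_in_box(cloud, box)) == 1L)
  list(cloud = pm_cloud_subset(cloud, keep), box = box,
       offsets = off, idx = keep)
}
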
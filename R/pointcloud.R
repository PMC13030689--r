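#' Canonical landmark names
#'
#' The six posterior pelvic landmarks handled throughout the package, in the
#' fixed order used for integer class labels (class k corresponds to
#' `pm_landmark_names()[k]`): left/right posterior superior iliac spine,
#' left/right iliac crest, and the L1 and L4 vertebral levels.
#'
#' @return Character vector of length 6.
#' @export
pm_landmark_names <- function() {
  c("PSIS_L", "PSIS_R", "IC_L", "IC_R", "L1", "L4")
}

#' Construct a point cloud
#'
#' A point cloud is an N x 3 matrix of coordinates in millimetres with
#' optional row-aligned per-point feature channels and scan metadata.
#'
#' @param positions numeric N x 3 matrix (mm), N >= 1, all finite.
#' @param features optional numeric N x F matrix, row-aligned with positions.
#' @param subject_id,scan_id optional identifiers.
#' @param posture optional posture tag, `"P1"` (upright) or `"P2"`
#'   (forward bending).
#' @return An object of class `pm_cloud`.
#' @export
pm_cloud <- function(positions, features = NULL, subject_id = NULL,
                     scan_id = NULL, posture = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an N x 3 matrix")
  if (nrow(positions) < 1L) stop("point cloud must contain at least one point")
  if (!all(is.finite(positions))) stop("positions must be finite")
  storage.mode(positions) <- "double"
  if (!is.null(features)) {
    features <- as.matrix(features)
    if (nrow(features) != nrow(positions)) {
      stop("features must be row-aligned with positions")
    }
    storage.mode(features) <- "double"
  }
  if (!is.null(posture) && !posture %in% c("P1", "P2")) {
    stop("posture must be \"P1\" or \"P2\"")
  }
  structure(
    list(positions = positions, features = features,
         subject_id = subject_id, scan_id = scan_id, posture = posture),
    class = "pm_cloud"
  )
}

#' @export
print.pm_cloud <- function(x, ...) {
  cat(sprintf("<pm_cloud> %d points", nrow(x$positions)))
  if (!is.null(x$features)) cat(sprintf(", %d feature channels", ncol(x$features)))
  if (!is.null(x$subject_id)) cat(sprintf(", subject %s", x$subject_id))
  if (!is.null(x$posture)) cat(sprintf(", posture %s", x$posture))
  cat("\n")
  rng <- apply(x$positions, 2, range)
  cat(sprintf("  extent (mm): x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a `pm_cloud`.
#' @return Integer point count.
#' @export
pm_n_points <- function(cloud) nrow(cloud$positions)

#' Subset a point cloud by point index
#'
#' Keeps positions, features and metadata consistent.
#'
#' @param cloud a `pm_cloud`.
#' @param idx integer index vector.
#' @return A `pm_cloud` with the selected points.
#' @export
pm_cloud_subset <- function(cloud, idx) {
  pm_cloud(cloud$positions[idx, , drop = FALSE],
           features = if (is.null(cloud$features)) NULL else cloud$features[idx, , drop = FALSE],
           subject_id = cloud$subject_id, scan_id = cloud$scan_id,
           posture = cloud$posture)
}

#' Construct a landmark set
#'
#' Named 3D coordinates (mm) for the six canonical landmarks. Landmarks may
#' be missing (row of `NA`), e.g. when a predicted landmark region contained
#' no points.
#'
#' @param coords a 6 x 3 matrix with rownames drawn from
#'   [pm_landmark_names()], or a named list of length-3 vectors. Missing
#'   landmarks may be omitted or set to `NA`.
#' @return An object of class `pm_landmarks`: a 6 x 3 matrix (rows in
#'   canonical order, `NA` rows marking missing landmarks).
#' @export
pm_landmarks <- function(coords) {
  nm <- pm_landmark_names()
  out <- matrix(NA_real_, 6, 3, dimnames = list(nm, c("x", "y", "z")))
  if (is.list(coords)) {
    bad <- setdiff(names(coords), nm)
    if (length(bad)) stop("unknown landmark name(s): ", paste(bad, collapse = ", "))
    for (k in names(coords)) out[k, ] <- as.numeric(coords[[k]])
  } else {
    coords <- as.matrix(coords)
    if (is.null(rownames(coords))) {
      if (nrow(coords) != 6L) stop("unnamed landmark matrix must have 6 rows")
      rownames(coords) <- nm
    }
    bad <- setdiff(rownames(coords), nm)
    if (length(bad)) stop("unknown landmark name(s): ", paste(bad, collapse = ", "))
    out[rownames(coords), ] <- coords
  }
  present <- stats::complete.cases(out)
  if (any(!is.finite(out[present, ]))) stop("present landmark coordinates must be finite")
  structure(out, class = c("pm_landmarks", "matrix", "array"))
}

#' @export
print.pm_landmarks <- function(x, ...) {
  cat("<pm_landmarks>\n")
  print(unclass(x))
  invisible(x)
}

#' Which landmarks are present (non-missing)?
#' @param lm a `pm_landmarks`.
#' @return Named logical vector of length 6.
#' @export
pm_landmarks_present <- function(lm) {
  stats::setNames(stats::complete.cases(unclass(lm)), pm_landmark_names())
}

#' Landmarks as a tibble
#' @param lm a `pm_landmarks`.
#' @return A tibble with columns name, x, y, z (missing landmarks as `NA`).
#' @export
pm_landmarks_tbl <- function(lm) {
  m <- unclass(lm)
  tibble::tibble(name = rownames(m), x = m[, 1], y = m[, 2], z = m[, 3])
}

#' Per-point label vector
#'
#' Integer class labels aligned with a companion point cloud. Two semantics
#' are used: `"roi"` (0 = other, 1 = pelvic region, C = 2) and `"landmark"`
#' (0 = background, 1..6 = landmark regions in canonical order, C = 7).
#'
#' @param labels integer vector of labels in `[0, n_classes)`.
#' @param n_classes number of classes C (>= 2).
#' @param semantics `"roi"`, `"landmark"`, or another tag.
#' @return An object of class `pm_labels` (integer vector with attributes).
#' @export
pm_labels <- function(labels, n_classes, semantics = "roi") {
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= n_classes)) {
    stop("labels must lie in [0, n_classes)")
  }
  structure(labels, n_classes = as.integer(n_classes), semantics = semantics,
            class = "pm_labels")
}

#' @export
print.pm_labels <- function(x, ...) {
  cat(sprintf("<pm_labels> %d points, %d classes (%s)\n",
              length(x), attr(x, "n_classes"), attr(x, "semantics")))
  print(table(factor(unclass(x), levels = 0:(attr(x, "n_classes") - 1L))))
  invisible(x)
}

#' @export
`[.pm_labels` <- function(x, i) {
  pm_labels(unclass(x)[i], attr(x, "n_classes"), attr(x, "semantics"))
}
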
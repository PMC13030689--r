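#' Rigid transform (rotation + translation)
#'
#' Coordinate convention throughout the package: x is lateral (right = +x),
#' y is vertical (up = +y), z is depth (toward the scanner = +z); units mm.
#' A transform maps a point p to `R p + t`, acting about the global origin.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation numeric length-3 vector (mm), default zero.
#' @param strict if `TRUE` (default), reject a non-orthonormal rotation.
#' @return An object of class `pm_transform`.
#' @export
pm_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                         strict = TRUE) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3 x 3")
  if (strict && !pm_is_rotation(rotation)) {
    stop("invalid rotation: not orthonormal with det +1 (tolerance 1e-6)")
  }
  translation <- as.numeric(translation)
  if (length(translation) != 3L || !all(is.finite(translation))) {
    stop("translation must be a finite length-3 vector")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "pm_transform")
}

#' @export
print.pm_transform <- function(x, ...) {
  ang <- pm_euler_from_rotation(x$rotation)
  cat(sprintf("<pm_transform> euler (deg): x %.2f  y %.2f  z %.2f | t (mm): %.2f %.2f %.2f\n",
              ang[1] * 180 / pi, ang[2] * 180 / pi, ang[3] * 180 / pi,
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Test a matrix for membership in the rotation group
#'
#' @param R 3 x 3 matrix.
#' @param tol tolerance on the orthonormality residual and on `det(R) - 1`.
#' @return `TRUE` if `t(R) %*% R` is the identity within `tol` (Frobenius
#'   norm) and `det(R)` is within `tol` of +1.
#' @export
pm_is_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L)) || !all(is.finite(R))) return(FALSE)
  resid <- norm(crossprod(R) - diag(3), type = "F")
  resid < tol && abs(det(R) - 1) < tol
}

#' Apply a rigid transform to a point cloud or coordinate matrix
#'
#' Positions are mapped as `R p + t`; features and metadata are untouched.
#'
#' @param cloud a `pm_cloud` or an N x 3 coordinate matrix.
#' @param transform a `pm_transform`.
#' @param strict if `TRUE` (default), error on a non-orthonormal rotation.
#' @return Object of the same type as `cloud` with transformed positions.
#' @export
pm_apply_transform <- function(cloud, transform, strict = TRUE) {
  if (strict && !pm_is_rotation(transform$rotation)) {
    stop("invalid rotation: not orthonormal with det +1 (tolerance 1e-6)")
  }
  tf <- function(P) {
    sweep(P %*% t(transform$rotation), 2, transform$translation, "+")
  }
  if (inherits(cloud, "pm_cloud")) {
    cloud$positions <- tf(cloud$positions)
    cloud
  } else if (inherits(cloud, "pm_landmarks")) {
    m <- unclass(cloud)
    ok <- stats::complete.cases(m)
    m[ok, ] <- tf(m[ok, , drop = FALSE])
    pm_landmarks(m)
  } else {
    tf(as.matrix(cloud))
  }
}

#' Invert a rigid transform
#' @param transform a `pm_transform`.
#' @return The inverse `pm_transform`.
#' @export
pm_transform_inverse <- function(transform) {
  Rt <- t(transform$rotation)
  pm_transform(Rt, -as.numeric(Rt %*% transform$translation), strict = FALSE)
}

#' Compose two rigid transforms
#'
#' `pm_transform_compose(a, b)` returns the transform equivalent to applying
#' `b` first, then `a`.
#'
#' @param a,b `pm_transform` objects.
#' @return A `pm_transform`.
#' @export
pm_transform_compose <- function(a, b) {
  pm_transform(a$rotation %*% b$rotation,
               as.numeric(a$rotation %*% b$translation) + a$translation,
               strict = FALSE)
}

#' Project a matrix onto the rotation group
#'
#' Returns the orthonormal matrix with determinant +1 closest to `M` in
#' Frobenius norm: `U diag(1, 1, det(U V')) V'` from the singular value
#' decomposition `M = U S V'`. This is the normalization applied to the
#' 9 values regressed by the alignment network.
#'
#' @param M 3 x 3 matrix, finite.
#' @return A 3 x 3 rotation matrix.
#' @export
pm_svd_project <- function(M) {
  M <- as.matrix(M)
  if (!all(dim(M) == c(3L, 3L)) || !all(is.finite(M))) {
    stop("M must be a finite 3 x 3 matrix")
  }
  sv <- svd(M)
  if (sv$d[2] <= 1e-9 * max(sv$d[1], 1e-300)) {
    stop("degenerate input: at least two singular values are (near) zero")
  }
  s3 <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, s3)) %*% t(sv$v)
}

rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, -sa, 0, sa, ca), 3, 3, byrow = TRUE)
}
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, sa, 0, 1, 0, -sa, 0, ca), 3, 3, byrow = TRUE)
}
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

#' Euler angles from a rotation matrix
#'
#' The package-wide Euler convention is intrinsic x-y-z:
#' `R = Rx(theta_x) Ry(theta_y) Rz(theta_z)`. Near gimbal lock
#' (`|theta_y| = pi/2`) the decomposition is not unique; the tie-break sets
#' `theta_z = 0` and absorbs the remaining rotation into `theta_x`.
#'
#' @param R 3 x 3 rotation matrix.
#' @return Numeric vector `c(theta_x, theta_y, theta_z)` in radians, each in
#'   `(-pi, pi]`.
#' @export
pm_euler_from_rotation <- function(R) {
  if (!pm_is_rotation(R, tol = 1e-4)) stop("R must be a rotation matrix")
  s_y <- max(-1, min(1, R[1, 3]))
  ty <- asin(s_y)
  if (abs(s_y) < 1 - 1e-9) {
    tx <- atan2(-R[2, 3], R[3, 3])
    tz <- atan2(-R[1, 2], R[1, 1])
  } else {
    # gimbal lock: theta_z := 0, theta_x from the unambiguous elements
    tx <- atan2(sign(s_y) * R[2, 1], R[2, 2])
    tz <- 0
  }
  c(theta_x = tx, theta_y = ty, theta_z = tz)
}

#' Rotation matrix from Euler angles (intrinsic x-y-z)
#'
#' @param angles numeric length-3 vector `(theta_x, theta_y, theta_z)` in
#'   radians.
#' @return 3 x 3 rotation matrix `Rx(theta_x) Ry(theta_y) Rz(theta_z)`.
#' @export
pm_rotation_from_euler <- function(angles) {
  angles <- as.numeric(angles)
  if (length(angles) != 3L || !all(is.finite(angles))) {
    stop("angles must be a finite length-3 vector")
  }
  rot_x(angles[1]) %*% rot_y(angles[2]) %*% rot_z(angles[3])
}

#' Geodesic angle between two rotations
#'
#' The magnitude (radians) of the single rotation taking `Ra` to `Rb`.
#'
#' @param Ra,Rb rotation matrices.
#' @return Angle in `[0, pi]`.
#' @export
pm_rotation_angle <- function(Ra, Rb = diag(3)) {
  tr <- sum(diag(crossprod(Ra, Rb)))
  acos(max(-1, min(1, (tr - 1) / 2)))
}

#' Canonical-pose transform from landmarks
#'
#' Builds the rigid transform that standardizes a scan's pose from its
#' landmarks: translate so the midpoint of the bilateral PSIS lies at the
#' origin, rotate about the y axis to align the PSIS segment horizontally
#' (zero depth difference), then rotate about the x axis so L4 has zero
#' depth. The two rotation angles are determined jointly from the normal of
#' the plane spanned by the PSIS segment and the L4 offset, so that all
#' three canonical invariants hold exactly; the y-rotation sign is chosen so
#' PSIS_R ends at positive x.
#'
#' @param landmarks a `pm_landmarks` with PSIS_L, PSIS_R and L4 present.
#' @return A `pm_transform` `t` such that applying `t` yields: PSIS midpoint
#'   at the origin, equal z for PSIS_L/PSIS_R, and z = 0 for L4 (all within
#'   1e-6 mm).
#' @export
pm_canonicalize_pose <- function(landmarks) {
  m <- unclass(landmarks)
  need <- c("PSIS_L", "PSIS_R", "L4")
  missing <- need[!stats::complete.cases(m[need, , drop = FALSE])]
  if (length(missing)) {
    stop("missing landmark(s) required for canonicalization: ",
         paste(missing, collapse = ", "))
  }
  mid <- (m["PSIS_L", ] + m["PSIS_R", ]) / 2
  d <- m["PSIS_R", ] - m["PSIS_L", ]
  l <- m["L4", ] - mid
  if (sqrt(sum(d^2)) < 1e-9) stop("degenerate geometry: PSIS_L equals PSIS_R")
  n <- c(d[2] * l[3] - d[3] * l[2],
         d[3] * l[1] - d[1] * l[3],
         d[1] * l[2] - d[2] * l[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-9) stop("degenerate geometry: L4 collinear with the PSIS segment")
  build <- function(sigma) {
    u <- sigma * n / nn
    # Rx(a) Ry(b) maps u to +z  <=>  u = (-sin b cos a, sin a, cos b cos a)
    a <- asin(max(-1, min(1, u[2])))
    b <- atan2(-u[1], u[3])
    rot_x(a) %*% rot_y(b)
  }
  R <- build(1)
  if ((R %*% d)[1] < 0) R <- build(-1)
  pm_transform(R, -as.numeric(R %*% mid))
}

#' Serialize a rigid transform to JSON
#'
#' Flat record with the rotation in row-major order and the Euler
#' convention tag, so transforms can be exchanged with other tools.
#'
#' @param transform a `pm_transform`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
pm_transform_to_json <- function(transform, path = NULL) {
  rec <- list(rotation = as.numeric(t(transform$rotation)),
              translation = as.numeric(transform$translation),
              euler_convention = "intrinsic-xyz")
  js <- jsonlite::toJSON(rec, digits = NA, auto_unbox = FALSE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' Deserialize a rigid transform from JSON
#'
#' @param json a JSON string or a path to a JSON file produced by
#'   [pm_transform_to_json()].
#' @return A `pm_transform`.
#' @export
pm_transform_from_json <- function(json) {
  rec <- jsonlite::fromJSON(json)
  if (!identical(rec$euler_convention, "intrinsic-xyz")) {
    stop("unsupported euler_convention: ", rec$euler_convention)
  }
  pm_transform(matrix(rec$rotation, 3, 3, byrow = TRUE), rec$translation)
}
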
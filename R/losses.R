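#' Loss weights
#'
#' @param class_weights per-class weights for the NLL term (`NULL` =
#'   uniform, or `"inverse_frequency"` resolved at training time against the
#'   label distribution).
#' @param class_weight_exponent exponent applied to the inverse-frequency
#'   weights (1 = plain inverse frequency; smaller values moderate the
#'   imbalance correction; default 0.75, which keeps rare landmark classes
#'   represented without over-painting their decision regions).
#' @param lambda_rot weight of the rotation orthonormality regularizer
#'   (default 0.1).
#' @param lambda_euler weight of the Euler-angle term (default 1.0).
#' @param lambda_dist weight of the marker-centre distance term
#'   (default 10).
#' @return A `pm_loss_weights` list.
#' @export
pm_loss_weights <- function(class_weights = NULL, class_weight_exponent = 0.75,
                            lambda_rot = 0.1, lambda_euler = 1.0,
                            lambda_dist = 10) {
  if (lambda_rot < 0 || lambda_euler < 0 || lambda_dist < 0) {
    stop("loss weights must be non-negative")
  }
  if (is.numeric(class_weights) && any(class_weights < 0)) {
    stop("class weights must be non-negative")
  }
  if (class_weight_exponent < 0 || class_weight_exponent > 1) {
    stop("class_weight_exponent must be in [0, 1]")
  }
  structure(list(class_weights = class_weights,
                 class_weight_exponent = class_weight_exponent,
                 lambda_rot = lambda_rot,
                 lambda_euler = lambda_euler, lambda_dist = lambda_dist),
            class = "pm_loss_weights")
}

resolve_class_weights <- function(w, labels, n_classes, exponent = 1) {
  if (is.null(w)) return(rep(1, n_classes))
  if (identical(w, "inverse_frequency")) {
    cnt <- tabulate(as.integer(labels) + 1L, nbins = n_classes)
    wi <- ifelse(cnt > 0, (length(labels) / (n_classes * cnt))^exponent, 0)
    return(wi)
  }
  if (length(w) != n_classes) stop("class weights length must equal n_classes")
  as.numeric(w)
}

#' Weighted negative log-likelihood over per-point log-probabilities
#'
#' `-(1/N) sum_i w_{y_i} log p_{i, y_i}`: the mean over points of the
#' class-weighted negative log-probability of each point's true class.
#'
#' @param log_probs N x C matrix of log-probabilities (rows log-sum-exp
#'   to 0).
#' @param labels integer labels in `[0, C)` (a `pm_labels` or plain
#'   vector).
#' @param class_weights optional length-C weight vector (default uniform).
#' @return Scalar loss.
#' @export
pm_nll_loss <- function(log_probs, labels, class_weights = NULL) {
  nll_with_grad(log_probs, labels, class_weights)$loss
}

nll_with_grad <- function(log_probs, labels, class_weights = NULL) {
  y <- as.integer(labels)
  N <- nrow(log_probs)
  C <- ncol(log_probs)
  if (length(y) != N) stop("labels length must match log_probs rows")
  if (any(y < 0L | y >= C)) stop("labels out of range for C classes")
  w <- resolve_class_weights(class_weights, y, C)
  sel <- cbind(seq_len(N), y + 1L)
  wy <- w[y + 1L]
  loss <- -sum(wy * log_probs[sel]) / N
  dlogp <- matrix(0, N, C)
  dlogp[sel] <- -wy / N
  list(loss = loss, dlogp = dlogp)
}

#' Mean point-wise Euclidean distance between index-paired clouds
#'
#' Points are paired by index (same point identity), not by nearest
#' neighbour.
#'
#' @param pred,ref `pm_cloud`s or N x 3 matrices with equal point counts.
#' @return Scalar mean distance in mm.
#' @export
pm_point_set_distance <- function(pred, ref) {
  P <- if (inherits(pred, "pm_cloud")) pred$positions else as.matrix(pred)
  Q <- if (inherits(ref, "pm_cloud")) ref$positions else as.matrix(ref)
  if (nrow(P) != nrow(Q)) stop("point counts must match (index-paired distance)")
  mean(sqrt(rowSums((P - Q)^2)))
}

#' Rotation orthonormality regularizer
#'
#' `|| I - R'R ||_F`; zero exactly when `R` is orthonormal (any
#' determinant sign -- reflections are excluded by the SVD projection, not
#' by this term).
#'
#' @param R 3 x 3 matrix.
#' @return Scalar.
#' @export
pm_rotation_regularization <- function(R) {
  norm(diag(3) - crossprod(as.matrix(R)), type = "F")
}

rotation_reg_grad <- function(R, eps = 1e-12) {
  E <- diag(3) - crossprod(R)
  f <- norm(E, type = "F")
  if (f < eps) return(list(loss = f, dR = matrix(0, 3, 3)))
  list(loss = f, dR = -2 * R %*% E / f)
}

#' Euler-angle loss between two rotations
#'
#' The l2 distance between the intrinsic x-y-z Euler-angle vectors of the
#' two rotations (see [pm_euler_from_rotation()]).
#'
#' @param Rhat,Rref rotation matrices.
#' @return Scalar, radians.
#' @export
pm_euler_angle_loss <- function(Rhat, Rref) {
  sqrt(sum((pm_euler_from_rotation(Rhat) - pm_euler_from_rotation(Rref))^2))
}

# Exact backward of the SVD projection M -> R = U V' (orthogonal polar
# factor): with G = dL/dR and ~G = U' G V, dL/d~M has off-diagonal entries
# (~G_ij - ~G_ji) / (s_i + s_j), zero diagonal, and dL/dM = U dL/d~M V'.
# Scale directions of M receive zero gradient, which keeps the raw output
# bounded during training. Falls back to the identity (straight-through)
# map in the rare reflection case det(UV') < 0.
svd_project_bwd <- function(M, G) {
  sv <- svd(M)
  if (det(sv$u %*% t(sv$v)) < 0) return(G)
  Gt <- crossprod(sv$u, G %*% sv$v)
  K <- matrix(0, 3, 3)
  for (i in 1:2) for (j in (i + 1):3) {
    w <- (Gt[i, j] - Gt[j, i]) / max(sv$d[i] + sv$d[j], 1e-8)
    K[i, j] <- w
    K[j, i] <- -w
  }
  sv$u %*% K %*% t(sv$v)
}

# central finite differences of the Euler term w.r.t. the predicted matrix;
# each probe is re-projected onto the rotation group
euler_loss_grad_fd <- function(Rhat, Rref, h = 1e-5) {
  g <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Rp <- Rhat; Rp[i, j] <- Rp[i, j] + h
    Rm <- Rhat; Rm[i, j] <- Rm[i, j] - h
    g[i, j] <- (pm_euler_angle_loss(pm_svd_project(Rp), Rref) -
                  pm_euler_angle_loss(pm_svd_project(Rm), Rref)) / (2 * h)
  }
  g
}

#' Total alignment loss
#'
#' `L_pts + lambda_rot * L_rot + lambda_euler * L_euler`: the mean
#' point-wise distance between the predicted-transformed and reference
#' points, the orthonormality regularizer on the predicted matrix, and the
#' Euler-angle distance between predicted and reference rotations.
#'
#' @param pred_cloud,ref_cloud index-paired clouds (predicted-transformed
#'   and reference).
#' @param Rhat predicted rotation (or raw 3 x 3 matrix).
#' @param Rref reference rotation.
#' @param weights a `pm_loss_weights`.
#' @return Scalar total loss with the three components attached as
#'   attributes `pts`, `rot`, `euler`.
#' @export
pm_align_total_loss <- function(pred_cloud, ref_cloud, Rhat, Rref,
                                weights = pm_loss_weights()) {
  pts <- pm_point_set_distance(pred_cloud, ref_cloud)
  rot <- pm_rotation_regularization(Rhat)
  eul <- pm_euler_angle_loss(pm_svd_project(Rhat), Rref)
  total <- pts + weights$lambda_rot * rot + weights$lambda_euler * eul
  structure(total, pts = pts, rot = rot, euler = eul)
}

#' Marker-centre distance loss
#'
#' Mean Euclidean distance between predicted and ground-truth marker
#' centres over the markers present in the ground truth. Markers absent
#' from the ground truth are excluded; a marker present in the ground truth
#' but unpredicted contributes `missing_penalty_mm`.
#'
#' @param pred,gt `pm_landmarks`.
#' @param missing_penalty_mm distance charged for an unpredicted marker
#'   (default 50 mm, on the order of the ROI margin).
#' @return Scalar mean distance in mm.
#' @export
pm_marker_distance_loss <- function(pred, gt, missing_penalty_mm = 50) {
  gm <- unclass(gt); pmat <- unclass(pred)
  valid <- which(stats::complete.cases(gm))
  if (!length(valid)) stop("no valid markers in ground truth")
  d <- vapply(valid, function(k) {
    if (all(is.finite(pmat[k, ]))) sqrt(sum((pmat[k, ] - gm[k, ])^2))
    else missing_penalty_mm
  }, numeric(1))
  mean(d)
}

#' Total landmark loss
#'
#' `L_NLL + lambda_dist * L_dist` over per-point landmark-region labels and
#' marker centres.
#'
#' @param log_probs N x 7 log-probabilities.
#' @param labels landmark-region labels (0 background, 1..6 markers).
#' @param pred_centers,gt_centers `pm_landmarks`.
#' @param weights a `pm_loss_weights` (`lambda_dist` default 10).
#' @return Scalar total loss with components attached as attributes `nll`
#'   and `dist`.
#' @export
pm_landmark_total_loss <- function(log_probs, labels, pred_centers, gt_centers,
                                   weights = pm_loss_weights()) {
  nll <- pm_nll_loss(log_probs, labels, weights$class_weights)
  dist <- pm_marker_distance_loss(pred_centers, gt_centers)
  structure(nll + weights$lambda_dist * dist, nll = nll, dist = dist)
}

#' Soft (probability-weighted) marker centres
#'
#' Differentiable surrogate for hard-label centroids used during training:
#' the centre of marker class k is the coordinate average of all points
#' weighted by their predicted probability of class k.
#'
#' @param log_probs N x 7 log-probabilities.
#' @param positions N x 3 coordinates (mm).
#' @return A `pm_landmarks` of soft centres (always defined).
#' @export
pm_soft_centers <- function(log_probs, positions) {
  p <- exp(log_probs)
  out <- matrix(NA_real_, 6, 3)
  for (k in 1:6) {
    wk <- p[, k + 1L]
    S <- sum(wk)
    out[k, ] <- colSums(positions * wk) / S
  }
  rownames(out) <- pm_landmark_names()
  pm_landmarks(out)
}

# soft-centre distance loss and its gradient w.r.t. log-probabilities
soft_center_loss_grad <- function(log_probs, positions, gt) {
  p <- exp(log_probs)
  gm <- unclass(gt)
  valid <- which(stats::complete.cases(gm))
  if (!length(valid)) stop("no valid markers in ground truth")
  K <- length(valid)
  dlogp <- matrix(0, nrow(log_probs), ncol(log_probs))
  loss <- 0
  for (k in valid) {
    wk <- p[, k + 1L]
    S <- sum(wk)
    m_hat <- colSums(positions * wk) / S
    u <- m_hat - gm[k, ]
    nu <- sqrt(sum(u^2))
    loss <- loss + nu / K
    if (nu > 1e-12) {
      # dL/dp_ik = u' (x_i - m_hat) / (K S ||u||), then dlogp = p * dL/dp
      dldp <- as.numeric(sweep(positions, 2, m_hat) %*% (u / nu)) / (K * S)
      dlogp[, k + 1L] <- dldp * wk
    }
  }
  list(loss = loss, dlogp = dlogp)
}
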
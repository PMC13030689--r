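#' Per-class intersection-over-union and recall
#'
#' `IoU_c = TP / (TP + FP + FN)`, `recall_c = TP / (TP + FN)`. A class
#' absent from both prediction and truth has undefined metrics and is
#' reported as `NA`.
#'
#' @param pred,gt aligned label vectors (`pm_labels` or integer).
#' @param classes integer class ids to report (default: all classes of the
#'   label vectors).
#' @return A tibble with columns `class`, `iou`, `recall`, `tp`, `fp`,
#'   `fn`.
#' @export
pm_iou_recall <- function(pred, gt, classes = NULL) {
  p <- as.integer(pred); g <- as.integer(gt)
  if (length(p) != length(g)) stop("label vectors must be aligned")
  if (is.null(classes)) {
    nc <- max(attr(pred, "n_classes") %||% (max(p, g) + 1L),
              attr(gt, "n_classes") %||% (max(p, g) + 1L))
    classes <- 0:(nc - 1L)
  }
  rows <- lapply(classes, function(cl) {
    tp <- sum(p == cl & g == cl)
    fp <- sum(p == cl & g != cl)
    fn <- sum(p != cl & g == cl)
    denom <- tp + fp + fn
    tibble::tibble(class = cl,
                   iou = if (denom == 0) NA_real_ else tp / denom,
                   recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
                   tp = tp, fp = fp, fn = fn)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-landmark Euclidean localization errors
#'
#' @param pred,gt `pm_landmarks`.
#' @return A tibble with columns `landmark`, `error_mm` (`NA` when the
#'   prediction or the ground truth is missing) and `missing` (prediction
#'   missing while ground truth present).
#' @export
pm_localization_errors <- function(pred, gt) {
  pmat <- unclass(pred); gmat <- unclass(gt)
  nm <- pm_landmark_names()
  err <- rep(NA_real_, 6)
  miss <- rep(FALSE, 6)
  for (k in seq_len(6)) {
    gt_ok <- all(is.finite(gmat[k, ]))
    pr_ok <- all(is.finite(pmat[k, ]))
    if (gt_ok && pr_ok) err[k] <- sqrt(sum((pmat[k, ] - gmat[k, ])^2))
    if (gt_ok && !pr_ok) miss[k] <- TRUE
  }
  tibble::tibble(landmark = nm, error_mm = err, missing = miss)
}

#' Summarize localization errors
#'
#' Overall median, per-landmark medians, subject-level mean (unweighted
#' mean of per-subject means) with a Student-t 95% confidence interval over
#' subjects, and the error CDF at 1 mm steps.
#'
#' @param errors tibble with columns `error_mm`, `subject_id` and
#'   optionally `landmark` (e.g. from [pm_run_configuration()]).
#' @param conf confidence level (default 0.95).
#' @return A `pm_eval_report` list.
#' @export
pm_summarize_errors <- function(errors, conf = 0.95) {
  stopifnot(all(c("error_mm", "subject_id") %in% names(errors)))
  e <- errors$error_mm
  n_missing <- sum(is.na(e))
  ok <- !is.na(e)
  per_landmark <- NULL
  if ("landmark" %in% names(errors)) {
    agg <- stats::aggregate(error_mm ~ landmark, data = errors[ok, ],
                            FUN = stats::median)
    per_landmark <- tibble::tibble(landmark = agg$landmark,
                                   median_mm = agg$error_mm)
  }
  subj_means <- tapply(e[ok], errors$subject_id[ok], mean)
  ns <- length(subj_means)
  smean <- mean(subj_means)
  ci <- if (ns >= 2) {
    se <- stats::sd(subj_means) / sqrt(ns)
    smean + c(-1, 1) * stats::qt(1 - (1 - conf) / 2, ns - 1) * se
  } else c(NA_real_, NA_real_)
  emax <- if (any(ok)) ceiling(max(e[ok])) else 0
  thr <- seq(0, max(1, emax), by = 1)
  cdf <- tibble::tibble(threshold_mm = thr,
                        fraction = vapply(thr, function(t) {
                          sum(e[ok] <= t) / length(e)
                        }, numeric(1)))
  structure(list(median_mm = stats::median(e[ok]),
                 per_landmark = per_landmark,
                 subject_mean_mm = smean,
                 subject_ci_mm = ci,
                 n_subjects = ns,
                 n_errors = sum(ok),
                 n_missing = n_missing,
                 cdf = cdf),
            class = "pm_eval_report")
}

#' @export
print.pm_eval_report <- function(x, ...) {
  cat("<pm_eval_report>\n")
  cat(sprintf("  median error: %.2f mm over %d landmark instances (%d missing)\n",
              x$median_mm, x$n_errors, x$n_missing))
  cat(sprintf("  subject-level mean (n = %d): %.2f mm (95%% CI %.2f-%.2f)\n",
              x$n_subjects, x$subject_mean_mm, x$subject_ci_mm[1],
              x$subject_ci_mm[2]))
  if (!is.null(x$per_landmark)) {
    cat("  per-landmark medians (mm):\n")
    for (i in seq_len(nrow(x$per_landmark))) {
      cat(sprintf("    %-7s %.2f\n", x$per_landmark$landmark[i],
                  x$per_landmark$median_mm[i]))
    }
  }
  invisible(x)
}

#' Paired inter-landmark distances per repeated scan
#'
#' The three measurement regions are the distances PSIS_L-PSIS_R,
#' IC_L-IC_R and L1-L4. A repeat with either landmark of a pair missing
#' yields `NA` for that region.
#'
#' @param records list of records with `landmarks`, `subject_id`, `visit`,
#'   `rep` (e.g. dataset entries carrying predicted or ground-truth
#'   landmark sets).
#' @return Long tibble: `subject_id`, `visit`, `rep`, `region`,
#'   `distance_mm`.
#' @export
pm_paired_distance_series <- function(records) {
  pairs <- list("PSIS_L-PSIS_R" = c("PSIS_L", "PSIS_R"),
                "IC_L-IC_R" = c("IC_L", "IC_R"),
                "L1-L4" = c("L1", "L4"))
  rows <- lapply(records, function(r) {
    m <- unclass(r$landmarks)
    d <- vapply(pairs, function(p) {
      a <- m[p[1], ]; b <- m[p[2], ]
      if (all(is.finite(a)) && all(is.finite(b))) sqrt(sum((a - b)^2))
      else NA_real_
    }, numeric(1))
    tibble::tibble(subject_id = r$subject_id, visit = r$visit, rep = r$rep,
                   region = names(pairs), distance_mm = unname(d))
  })
  do.call(rbind, rows)
}

# ICC(2,1): two-way random effects, absolute agreement, single measure,
# with the F-based confidence interval. x: n x k matrix (rows = units,
# columns = repeats).
icc21 <- function(x, conf = 0.95) {
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) return(list(icc = NA_real_, lo = NA_real_, hi = NA_real_))
  mu <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  MSR <- k * sum((rm_ - mu)^2) / (n - 1)
  MSC <- n * sum((cm - mu)^2) / (k - 1)
  MSE <- sum((x - outer(rm_, cm, "+") + mu)^2) / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  if (abs(denom) < 1e-12) return(list(icc = NA_real_, lo = NA_real_, hi = NA_real_))
  icc <- (MSR - MSE) / denom
  alpha <- 1 - conf
  if (MSE < 1e-12 && MSC < 1e-12) {
    # perfect within-unit agreement: estimate 1 with a degenerate interval
    return(list(icc = icc, lo = icc, hi = icc))
  }
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  F1 <- stats::qf(1 - alpha / 2, n - 1, v)
  F2 <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (MSR - F1 * MSE) /
    (F1 * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  hi <- n * (F2 * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * F2 * MSR)
  list(icc = icc, lo = max(-1, min(lo, icc)), hi = min(1, max(hi, icc)))
}

#' Within-visit repeatability: pooled STD, CV and ICC per region
#'
#' STD is the pooled within-visit standard deviation (variances pooled with
#' their degrees of freedom); CV is that STD as a percentage of the grand
#' mean, so a constant offset between subjects does not inflate it. ICC is
#' the two-way random-effects absolute-agreement single-measure form
#' (ICC(2,1), the standard choice for repeated measurements of the same
#' quantity) over subject-visit units x repeats, with an F-based 95% CI;
#' `type = "ICC3"` switches to the consistency form ICC(3,1). Visits with
#' more repeats than the common minimum are truncated to keep the two-way
#' layout balanced. Data with zero total variance yield a missing ICC.
#'
#' @param series long tibble from [pm_paired_distance_series()].
#' @param conf confidence level (default 0.95).
#' @param type `"ICC2"` (absolute agreement, default) or `"ICC3"`
#'   (consistency).
#' @return A `pm_repeatability_report` tibble: `region`, `std_mm`,
#'   `cv_pct`, `icc`, `icc_lo`, `icc_hi`, `n_units`, `k_repeats`.
#' @export
pm_repeatability <- function(series, conf = 0.95, type = c("ICC2", "ICC3")) {
  type <- match.arg(type)
  rows <- lapply(unique(series$region), function(rg) {
    s <- series[series$region == rg & !is.na(series$distance_mm), ]
    s$unit <- paste(s$subject_id, s$visit, sep = "|")
    counts <- table(s$unit)
    keep_units <- names(counts)[counts >= 2]
    s <- s[s$unit %in% keep_units, ]
    if (length(keep_units) < 2) {
      return(tibble::tibble(region = rg, std_mm = NA_real_, cv_pct = NA_real_,
                            icc = NA_real_, icc_lo = NA_real_, icc_hi = NA_real_,
                            n_units = length(keep_units), k_repeats = NA_integer_))
    }
    # pooled within-visit STD and CV
    ss <- 0; df <- 0
    for (u in keep_units) {
      d <- s$distance_mm[s$unit == u]
      ss <- ss + sum((d - mean(d))^2)
      df <- df + length(d) - 1
    }
    std <- sqrt(ss / df)
    cv <- 100 * std / mean(s$distance_mm)
    # balanced matrix for the ICC: truncate to the common minimum repeats
    kmin <- min(counts[keep_units])
    x <- t(vapply(keep_units, function(u) {
      s$distance_mm[s$unit == u][seq_len(kmin)]
    }, numeric(kmin)))
    ic <- if (type == "ICC2") icc21(x, conf) else icc31(x, conf)
    tibble::tibble(region = rg, std_mm = std, cv_pct = cv,
                   icc = ic$icc, icc_lo = ic$lo, icc_hi = ic$hi,
                   n_units = nrow(x), k_repeats = as.integer(kmin))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pm_repeatability_report", class(out))
  out
}

# ICC(3,1): two-way mixed effects, consistency, single measure
icc31 <- function(x, conf = 0.95) {
  n <- nrow(x); k <- ncol(x)
  mu <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  MSR <- k * sum((rm_ - mu)^2) / (n - 1)
  MSE <- sum((x - outer(rm_, cm, "+") + mu)^2) / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE
  if (abs(denom) < 1e-12) return(list(icc = NA_real_, lo = NA_real_, hi = NA_real_))
  icc <- (MSR - MSE) / denom
  if (MSE < 1e-12) return(list(icc = icc, lo = icc, hi = icc))
  alpha <- 1 - conf
  Fv <- MSR / MSE
  FL <- Fv / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
  FU <- Fv * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
  list(icc = icc, lo = max(-1, min((FL - 1) / (FL + k - 1), icc)),
       hi = min(1, max((FU - 1) / (FU + k - 1), icc)))
}

#' Hyperparameter sensitivity grid for the landmark stage
#'
#' Retrains the landmark network for each setting of the distance-loss
#' weight (at the reference labeling radius) and of the labeling radius
#' (at the reference weight), and tabulates the mean Euclidean centre
#' error on the test scans. The shared centre setting is evaluated once.
#'
#' @param train_scans,test_scans scan records.
#' @param cfg a `pm_train_config`.
#' @param lambdas distance-loss weights (default 5, 10, 15).
#' @param radii labeling radii in mm (default 10, 15, 20).
#' @param ref_lambda,ref_radius the fixed counterpart values (defaults 10
#'   and 10 mm).
#' @param seed evaluation seed.
#' @return A tibble: `parameter`, `value`, `lambda_dist`, `radius_mm`,
#'   `mean_error_mm`.
#' @export
pm_sensitivity_grid <- function(train_scans, test_scans,
                                cfg = pm_train_config(),
                                lambdas = c(5, 10, 15),
                                radii = c(10, 15, 20),
                                ref_lambda = 10, ref_radius = 10,
                                seed = 1L) {
  settings <- rbind(
    data.frame(parameter = "lambda_dist", value = lambdas,
               lambda_dist = lambdas, radius_mm = ref_radius),
    data.frame(parameter = "radius_mm",
               value = radii[radii != ref_radius],
               lambda_dist = ref_lambda,
               radius_mm = radii[radii != ref_radius]))
  rows <- lapply(seq_len(nrow(settings)), function(i) {
    st <- settings[i, ]
    cfg_i <- cfg
    cfg_i$radius_mm <- st$radius_mm
    w <- pm_loss_weights(lambda_dist = st$lambda_dist)
    fit <- pm_train_landmarknet(train_scans, cfg_i, w)
    errs <- lapply(seq_along(test_scans), function(j) {
      sc <- test_scans[[j]]
      can <- canonical_crop(sc, cfg_i, NULL,
                            seed = pm_child_seed(seed, 300 + j))
      n <- min(cfg_i$downsample_n, pm_n_points(can$cloud))
      ds <- pm_downsample(can$cloud, n, seed = pm_child_seed(seed, j))
      pred <- predict_landmarks_centered(ds, fit$net,
                                         pm_child_seed(seed, 600 + j))
      pm_localization_errors(pred, can$landmarks)$error_mm
    })
    tibble::tibble(parameter = st$parameter, value = st$value,
                   lambda_dist = st$lambda_dist, radius_mm = st$radius_mm,
                   mean_error_mm = mean(unlist(errs), na.rm = TRUE))
  })
  do.call(rbind, rows)
}
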
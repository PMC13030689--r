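# Deterministic generator of pelvic-like posterior surface scans with
# ground-truth landmarks. The surface is a smooth parametric height field
# z = f(x, y) over a lateral/vertical domain (x lateral, y vertical, z
# depth): lateral torso rounding, a lumbar depth profile, a buttock bulge
# below the PSIS level, a midline spinous groove, and local bumps/dimples
# at the six landmark sites so the networks see curvature cues, not only
# coordinates. All randomness is a pure function of (config, seed).

#' Sample a synthetic subject shape
#'
#' Draws torso scale, curvature and landmark-template parameters from
#' documented ranges (mm): lateral width 320-460, PSIS half-separation
#' 30-55, iliac-crest half-separation 110-150, L4 50-80 above the PSIS
#' level, L1 130-170 above L4, lumbar-curve amplitude 15-35, buttock bulge
#' 20-40, tissue-thickness (landmark bump amplitude) 5-12. Template
#' landmarks are mutually >= 40 mm apart by construction.
#'
#' @param seed integer seed; the shape is deterministic per seed.
#' @return A `pm_subject` list (scales in mm plus the 6 x 2 landmark
#'   template in the surface (x, y) parameter plane).
#' @export
pm_sample_subject <- function(seed = 1L) {
  p <- with_pm_seed(seed, list(
    width = stats::runif(1, 320, 460),
    depth = stats::runif(1, 40, 80),
    lumbar_amp = stats::runif(1, 15, 35),
    buttock_amp = stats::runif(1, 20, 40),
    tissue = stats::runif(1, 5, 12),
    psis_half = stats::runif(1, 30, 55),
    ic_half = stats::runif(1, 110, 150),
    ic_y = stats::runif(1, 30, 60),
    l4_y = stats::runif(1, 50, 80),
    l1_gap = stats::runif(1, 130, 170)
  ))
  p$y_lo <- -250; p$y_hi <- 450
  tmpl <- rbind(
    PSIS_L = c(-p$psis_half, 0),
    PSIS_R = c(p$psis_half, 0),
    IC_L = c(-p$ic_half, p$ic_y),
    IC_R = c(p$ic_half, p$ic_y),
    L1 = c(0, p$l4_y + p$l1_gap),
    L4 = c(0, p$l4_y))
  colnames(tmpl) <- c("x", "y")
  p$template <- tmpl
  p$seed <- as.integer(seed)
  structure(p, class = "pm_subject")
}

# surface height field; bend_amp > 0 models the forward-bending posture
surface_height <- function(x, y, shape, bend_amp = 0) {
  z <- -shape$depth * (2 * x / shape$width)^2 +
    shape$lumbar_amp * exp(-((y - 120) / 110)^2) +
    shape$buttock_amp * exp(-((y + 130) / 90)^2) -
    0.4 * shape$tissue * exp(-(x / 12)^2)
  tmpl <- shape$template
  bump <- c(PSIS_L = -1, PSIS_R = -1, IC_L = 0.6, IC_R = 0.6, L1 = 0.8, L4 = 0.8)
  sig <- c(PSIS_L = 8, PSIS_R = 8, IC_L = 12, IC_R = 12, L1 = 7, L4 = 7)
  for (k in rownames(tmpl)) {
    d2 <- (x - tmpl[k, 1])^2 + (y - tmpl[k, 2])^2
    z <- z + bump[k] * shape$tissue * exp(-d2 / (2 * sig[k]^2))
  }
  if (bend_amp > 0) {
    z <- z - bend_amp * pmax(0, (y - 100) / 250)^2
  }
  z
}

#' Scan recipe
#'
#' @param subject a `pm_subject`.
#' @param posture `"P1"` (upright) or `"P2"` (forward bending; the upper
#'   torso is smoothly displaced in depth).
#' @param preset `"tiny"` (20,000-60,000 points, the test scale) or
#'   `"full"` (200,000-600,000 points, the acquisition scale).
#' @param n_points explicit point-count target overriding the preset draw.
#' @param noise_sd surface noise standard deviation in mm (default 1, a
#'   typical structured-light magnitude).
#' @param occlusion remove a contiguous surface patch (incomplete arm
#'   abduction shadowing).
#' @param occlusion_frac fraction of points removed by the patch.
#' @param inclusion append an adjacent-region band above the scanned torso.
#' @param limb_fragment append lateral arm-fragment strips.
#' @param jitter_rot_deg,jitter_trans_mm pose jitter between repeated scans.
#' @param offset scan-frame offset (mm) placing the body in the scanner
#'   frame.
#' @param seed integer seed.
#' @return A `pm_recipe` list.
#' @export
pm_scan_recipe <- function(subject, posture = "P1",
                           preset = c("tiny", "full"), n_points = NULL,
                           noise_sd = 1, occlusion = FALSE,
                           occlusion_frac = 0.05, inclusion = FALSE,
                           limb_fragment = FALSE, jitter_rot_deg = 2,
                           jitter_trans_mm = 10, offset = c(0, 900, 600),
                           seed = 1L) {
  preset <- match.arg(preset)
  if (!posture %in% c("P1", "P2")) stop("posture must be P1 or P2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(subject = subject, posture = posture, preset = preset,
                 n_points = n_points, noise_sd = noise_sd,
                 occlusion = occlusion, occlusion_frac = occlusion_frac,
                 inclusion = inclusion, limb_fragment = limb_fragment,
                 jitter_rot_deg = jitter_rot_deg,
                 jitter_trans_mm = jitter_trans_mm,
                 offset = offset, seed = as.integer(seed)),
            class = "pm_recipe")
}

#' Generate one synthetic scan
#'
#' Samples the parametric surface to the target count with Gaussian surface
#' noise, places the six ground-truth landmarks on the noise-free surface,
#' applies the requested artifacts, and maps everything into the scan frame
#' with a small rigid pose jitter.
#'
#' @param recipe a `pm_recipe`.
#' @return A list with `cloud` (a `pm_cloud`), `landmarks`
#'   (a `pm_landmarks`, scan frame), `jitter` (the applied `pm_transform`)
#'   and `recipe`.
#' @export
pm_generate_scan <- function(recipe) {
  sh <- recipe$subject
  sd0 <- recipe$seed
  n <- recipe$n_points
  if (is.null(n)) {
    rng <- if (recipe$preset == "tiny") c(20000, 60000) else c(200000, 600000)
    n <- with_pm_seed(pm_child_seed(sd0, 1), round(stats::runif(1, rng[1], rng[2])))
  }
  bend <- if (recipe$posture == "P2") {
    with_pm_seed(pm_child_seed(sd0, 2), stats::runif(1, 60, 120))
  } else 0
  xy <- with_pm_seed(pm_child_seed(sd0, 3), {
    cbind(stats::runif(n, -sh$width / 2, sh$width / 2),
          stats::runif(n, sh$y_lo, sh$y_hi))
  })
  z <- surface_height(xy[, 1], xy[, 2], sh, bend)
  z <- z + with_pm_seed(pm_child_seed(sd0, 4), stats::rnorm(n, 0, recipe$noise_sd))
  P <- cbind(xy, z)

  tmpl <- sh$template
  lm <- cbind(tmpl,
              surface_height(tmpl[, 1], tmpl[, 2], sh, bend))
  colnames(lm) <- c("x", "y", "z")

  if (recipe$occlusion) {
    area <- sh$width * (sh$y_hi - sh$y_lo)
    r <- sqrt(recipe$occlusion_frac * area / pi)
    ctr <- with_pm_seed(pm_child_seed(sd0, 5), {
      c(stats::runif(1, -sh$width / 2 + r, sh$width / 2 - r),
        stats::runif(1, sh$y_lo + r, sh$y_hi - r))
    })
    keep <- (P[, 1] - ctr[1])^2 + (P[, 2] - ctr[2])^2 > r^2
    P <- P[keep, , drop = FALSE]
  }
  if (recipe$inclusion) {
    m <- round(0.04 * n)
    extra <- with_pm_seed(pm_child_seed(sd0, 6), {
      cbind(stats::runif(m, -sh$width / 2, sh$width / 2),
            stats::runif(m, sh$y_hi + 20, sh$y_hi + 120),
            stats::rnorm(m, -sh$depth / 2, 15))
    })
    P <- rbind(P, extra)
  }
  if (recipe$limb_fragment) {
    m <- round(0.03 * n)
    side <- with_pm_seed(pm_child_seed(sd0, 7), sample(c(-1, 1), 1))
    extra <- with_pm_seed(pm_child_seed(sd0, 8), {
      cbind(side * stats::runif(m, sh$width / 2 + 20, sh$width / 2 + 70),
            stats::runif(m, 0, sh$y_hi),
            stats::rnorm(m, -sh$depth, 12))
    })
    P <- rbind(P, extra)
  }

  ang <- with_pm_seed(pm_child_seed(sd0, 9),
                      stats::runif(3, -recipe$jitter_rot_deg,
                                   recipe$jitter_rot_deg)) * pi / 180
  tr <- with_pm_seed(pm_child_seed(sd0, 10),
                     stats::runif(3, -recipe$jitter_trans_mm,
                                  recipe$jitter_trans_mm))
  jit <- pm_transform(pm_rotation_from_euler(ang), tr + recipe$offset)
  P <- pm_apply_transform(P, jit)
  lm <- pm_apply_transform(pm_landmarks(lm), jit)

  cloud <- pm_cloud(P, subject_id = as.character(sh$seed), posture = recipe$posture)
  list(cloud = cloud, landmarks = lm, jitter = jit, recipe = recipe)
}

#' Generate a structured synthetic dataset
#'
#' Subjects x visits x repeats x postures. Repeats within a visit share the
#' subject shape and differ only by pose jitter, surface noise and point
#' resampling -- the structure the repeatability analysis assumes.
#'
#' @param n_subjects number of subjects.
#' @param visits visits per subject (default 1).
#' @param repeats_per_visit repeated scans per visit (2 or 3; default 2).
#' @param postures character vector of postures scanned per visit
#'   (default `"P1"`).
#' @param seed master seed.
#' @param preset,n_points,noise_sd forwarded to [pm_scan_recipe()].
#' @param ... further arguments forwarded to [pm_scan_recipe()].
#' @return A list of scan records; each record is the [pm_generate_scan()]
#'   output plus `subject_id`, `visit`, `rep`, `posture` and `scan_id`.
#' @export
pm_generate_dataset <- function(n_subjects, visits = 1L, repeats_per_visit = 2L,
                                postures = "P1", seed = 1L,
                                preset = "tiny", n_points = NULL,
                                noise_sd = 1, ...) {
  if (!repeats_per_visit %in% 2:3) stop("repeats_per_visit must be 2 or 3")
  out <- list()
  idx <- 0L
  for (s in seq_len(n_subjects)) {
    subj <- pm_sample_subject(pm_child_seed(seed, 1000 + s))
    for (v in seq_len(visits)) for (r in seq_len(repeats_per_visit)) {
      for (po in postures) {
        idx <- idx + 1L
        rec <- pm_scan_recipe(subj, posture = po, preset = preset,
                              n_points = n_points, noise_sd = noise_sd,
                              seed = pm_child_seed(seed, idx * 13 + s), ...)
        scan <- pm_generate_scan(rec)
        scan$subject_id <- sprintf("S%03d", s)
        scan$visit <- v
        scan$rep <- r
        scan$posture <- po
        scan$scan_id <- sprintf("S%03d_V%d_R%d_%s", s, v, r, po)
        scan$cloud$subject_id <- scan$subject_id
        scan$cloud$scan_id <- scan$scan_id
        out[[idx]] <- scan
      }
    }
  }
  out
}
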
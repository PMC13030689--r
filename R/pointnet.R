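# Set-abstraction / feature-propagation point networks. A set-abstraction
# (SA) stage selects centres by farthest-point sampling, gathers ball-query
# neighbourhoods, runs a shared MLP on (local offset, feature) rows and
# max-pools per neighbourhood; feature-propagation (FP) stages interpolate
# features back up with inverse-distance-squared weights over the 3 nearest
# centres and mix them with skip features. Grouping indices depend only on
# coordinates, so they are computed once per sample ("graph") and reused
# across epochs.

fps_indices <- function(P, m, seed = 1L) {
  start <- with_pm_seed(seed, sample.int(nrow(P), 1))
  as.integer(cpp_fps(P, as.integer(min(m, nrow(P))), start))
}

# K nearest neighbours within `radius` of each centre, padded by repeating
# the nearest source point when the ball holds fewer than K. Returns an
# M x K index matrix into `src`.
ball_query <- function(centers, src, radius, K) {
  cpp_ball_query(centers, src, radius, as.integer(K))
}

knn3_interp <- function(query, src) {
  r <- cpp_knn3(query, src)
  list(idx = r$idx, w = r$w)
}

#' Segmentation network configuration
#'
#' Hierarchy of set-abstraction stages (centre counts, ball radii in mm,
#' neighbourhood sizes, shared-MLP widths, optionally several grouping
#' scales per stage) followed by feature-propagation stages and a point-wise
#' head with dropout and log-softmax output. The `"full"` preset mirrors the
#' training-scale design (stages 1024/256/64/16, multi-scale grouping,
#' deepest width 512, 128-d propagated features); the `"tiny"` preset
#' (stages 256/64/32/8, width 128) runs training experiments at desk scale.
#'
#' @param preset `"tiny"` or `"full"`.
#' @param n_classes number of output classes C (2 for ROI, 7 for landmarks).
#' @param dropout dropout probability in the head (default 0.5).
#' @return A `pm_seg_config` list.
#' @export
pm_seg_config <- function(preset = c("tiny", "full"), n_classes = 2L,
                          dropout = 0.5) {
  preset <- match.arg(preset)
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (preset == "tiny") {
    sa <- list(
      list(npoint = 512L, radius = c(15, 30), K = c(8L, 16L),
           mlp = list(c(16, 16), c(32, 32))),
      list(npoint = 64L, radius = 60, K = 8L, mlp = list(c(64, 64))),
      list(npoint = 32L, radius = 120, K = 8L, mlp = list(c(64, 128))),
      list(npoint = 8L, radius = 240, K = 8L, mlp = list(c(128, 128))))
    fp_width <- c(64, 64, 64, 64)
    head <- 64
  } else {
    sa <- list(
      list(npoint = 1024L, radius = c(30, 60), K = c(16L, 32L),
           mlp = list(c(32, 32, 64), c(32, 32, 64))),
      list(npoint = 256L, radius = c(60, 120), K = c(16L, 32L),
           mlp = list(c(64, 64, 128), c(64, 64, 128))),
      list(npoint = 64L, radius = c(120, 240), K = c(16L, 32L),
           mlp = list(c(128, 128, 256), c(128, 128, 256))),
      list(npoint = 16L, radius = c(240, 480), K = c(16L, 32L),
           mlp = list(c(256, 256, 256), c(256, 256, 256))))
    fp_width <- c(256, 256, 128, 128)
    head <- 128
  }
  np <- vapply(sa, function(s) s$npoint, integer(1))
  if (any(diff(np) >= 0)) stop("stage point counts must be strictly decreasing")
  structure(list(preset = preset, n_classes = as.integer(n_classes),
                 in_channels = 6L, sa = sa, fp_width = fp_width,
                 head = head, dropout = dropout),
            class = "pm_seg_config")
}

#' Alignment network configuration
#'
#' Two set-abstraction stages, a global-aggregation stage, and fully
#' connected layers regressing 9 values reshaped to a 3 x 3 matrix that is
#' normalized onto the rotation group by SVD projection inside the forward
#' pass. The `"full"` preset downsamples to 512 and 128 points; `"tiny"`
#' runs at desk scale.
#'
#' @param preset `"tiny"` or `"full"`.
#' @return A `pm_align_config` list.
#' @export
pm_align_config <- function(preset = c("tiny", "full")) {
  preset <- match.arg(preset)
  if (preset == "tiny") {
    sa <- list(
      list(npoint = 128L, radius = 60, K = 16L, mlp = list(c(32, 64))),
      list(npoint = 32L, radius = 150, K = 8L, mlp = list(c(64, 128))))
    global_mlp <- c(128, 256)
    fc <- c(128, 64)
  } else {
    sa <- list(
      list(npoint = 512L, radius = 40, K = 32L, mlp = list(c(64, 64, 128))),
      list(npoint = 128L, radius = 100, K = 32L, mlp = list(c(128, 128, 256))),
      list(npoint = 32L, radius = 240, K = 16L, mlp = list(c(256, 256, 256))))
    global_mlp <- c(256, 512)
    fc <- c(256, 128)
  }
  structure(list(preset = preset, in_channels = 6L, sa = sa,
                 global_mlp = global_mlp, fc = fc),
            class = "pm_align_config")
}

sa_out_width <- function(stage) sum(vapply(stage$mlp, function(w) w[length(w)], numeric(1)))

#' Build a segmentation network
#'
#' Initializes the weights of a set-abstraction / feature-propagation
#' segmentation network from a configuration.
#'
#' @param config a `pm_seg_config`.
#' @param seed weight-initialization seed.
#' @return A `pm_seg_net` (environment holding parameters and config).
#' @export
pm_seg_net <- function(config = pm_seg_config(), seed = 1L) {
  net <- nn_new()
  net$config <- config
  net$kind <- "seg"
  cin <- config$in_channels
  widths <- integer(length(config$sa))
  for (l in seq_along(config$sa)) {
    stage <- config$sa[[l]]
    for (s in seq_along(stage$mlp)) {
      mlp_init(net, sprintf("sa%d.s%d", l, s), c(3L + cin, stage$mlp[[s]]),
               pm_child_seed(seed, 100 * l + s))
    }
    widths[l] <- sa_out_width(stage)
    cin <- widths[l]
  }
  skip <- c(config$in_channels, widths[-length(widths)])
  below <- widths[length(widths)]
  for (l in rev(seq_along(config$sa))) {
    mlp_init(net, sprintf("fp%d", l), c(below + skip[l], config$fp_width[l]),
             pm_child_seed(seed, 200 + l))
    below <- config$fp_width[l]
  }
  # the head sees the propagated features plus the raw input channels, so
  # absolute position within the cloud stays directly visible to it
  mlp_init(net, "head.hidden", c(config$fp_width[1] + config$in_channels,
                                 config$head),
           pm_child_seed(seed, 300))
  mlp_init(net, "head.out", c(config$head, config$n_classes),
           pm_child_seed(seed, 301), bn_last = FALSE, relu_last = FALSE)
  class(net) <- c("pm_seg_net", "environment")
  net
}

#' Build an alignment (rotation-regression) network
#'
#' @param config a `pm_align_config`.
#' @param seed weight-initialization seed.
#' @return A `pm_align_net` (environment).
#' @export
pm_align_net <- function(config = pm_align_config(), seed = 1L) {
  net <- nn_new()
  net$config <- config
  net$kind <- "align"
  cin <- config$in_channels
  for (l in seq_along(config$sa)) {
    stage <- config$sa[[l]]
    for (s in seq_along(stage$mlp)) {
      mlp_init(net, sprintf("sa%d.s%d", l, s), c(3L + cin, stage$mlp[[s]]),
               pm_child_seed(seed, 100 * l + s))
    }
    cin <- sa_out_width(stage)
  }
  mlp_init(net, "global", c(3L + cin, config$global_mlp),
           pm_child_seed(seed, 250))
  gout <- config$global_mlp[length(config$global_mlp)]
  # FC trunk sees one row per sample; batch norm is skipped there
  mlp_init(net, "fc", c(gout, config$fc, 9L), pm_child_seed(seed, 260),
           bn = FALSE, bn_last = FALSE, relu_last = FALSE)
  # start from the identity rotation: small final weights, identity bias
  Lfc <- length(config$fc) + 1L
  net$par[[paste0("fc.W", Lfc)]] <- net$par[[paste0("fc.W", Lfc)]] * 0.01
  net$par[[paste0("fc.b", Lfc)]] <- as.numeric(t(diag(3)))
  class(net) <- c("pm_align_net", "environment")
  net
}

# Precompute sampling/grouping/interpolation indices for one cloud.
pm_build_graph <- function(P, config, seed = 1L) {
  levels <- list(P)
  sa <- vector("list", length(config$sa))
  for (l in seq_along(config$sa)) {
    stage <- config$sa[[l]]
    src <- levels[[l]]
    if (nrow(src) < 2L) stop("architecture constraint: too few points for stage ", l)
    ctr_idx <- fps_indices(src, stage$npoint, pm_child_seed(seed, 10 + l))
    centers <- src[ctr_idx, , drop = FALSE]
    scales <- vector("list", length(stage$mlp))
    for (s in seq_along(stage$mlp)) {
      gi <- ball_query(centers, src, stage$radius[s], stage$K[s])
      flat <- as.integer(t(gi))  # group-major: rows of group j are (j-1)*K + 1:K
      local <- cpp_group_local(src, gi, centers)
      scales[[s]] <- list(flat = flat, local = local, K = stage$K[s])
    }
    sa[[l]] <- list(ctr_idx = ctr_idx, scales = scales, M = nrow(centers))
    levels[[l + 1]] <- centers
  }
  fp <- vector("list", length(config$sa))
  if (!is.null(config$fp_width)) {
    for (l in seq_along(config$sa)) {
      fp[[l]] <- knn3_interp(levels[[l]], levels[[l + 1]])
    }
  }
  list(levels = levels, sa = sa, fp = fp)
}

maxpool_groups <- function(H, M, K) {
  cpp_maxpool_groups(H, as.integer(M), as.integer(K))
}

scatter_rows <- function(dG, idx, n) {
  cpp_scatter_rows(dG, as.integer(idx), as.integer(n))
}

sa_stage_fwd <- function(net, l, graph, Fin, train) {
  g <- graph$sa[[l]]
  outs <- list(); caches <- list()
  for (s in seq_along(g$scales)) {
    sc <- g$scales[[s]]
    G <- cbind(sc$local, Fin[sc$flat, , drop = FALSE])
    fwd <- mlp_fwd(net, sprintf("sa%d.s%d", l, s), G, train)
    mp <- maxpool_groups(fwd$Y, g$M, sc$K)
    outs[[s]] <- mp$Y
    caches[[s]] <- list(fwd = fwd, argrow = mp$argrow, flat = sc$flat,
                        n_in = nrow(Fin), cin = ncol(Fin), Hrows = nrow(fwd$Y))
  }
  list(Y = do.call(cbind, outs), caches = caches)
}

sa_stage_bwd <- function(net, l, stage_cache, dY) {
  dFin <- NULL
  col0 <- 0L
  for (s in seq_along(stage_cache$caches)) {
    cc <- stage_cache$caches[[s]]
    C <- ncol(cc$fwd$Y)
    dYs <- dY[, col0 + seq_len(C), drop = FALSE]
    col0 <- col0 + C
    dH <- cpp_maxpool_bwd(dYs, cc$argrow, cc$Hrows)
    dG <- mlp_bwd(net, sprintf("sa%d.s%d", l, s), cc$fwd, dH)
    dF <- scatter_rows(dG[, -(1:3), drop = FALSE], cc$flat, cc$n_in)
    dFin <- if (is.null(dFin)) dF else dFin + dF
  }
  dFin
}

# Segmentation forward pass: returns per-point log-probabilities plus a
# cache consumed by pm_seg_backward during training.
pm_seg_forward <- function(net, features, graph, train = FALSE,
                           dropout_seed = 1L) {
  cfg <- net$config
  F <- features
  sa_caches <- vector("list", length(cfg$sa))
  feats <- list(F)
  for (l in seq_along(cfg$sa)) {
    st <- sa_stage_fwd(net, l, graph, F, train)
    sa_caches[[l]] <- st
    F <- st$Y
    feats[[l + 1]] <- F
  }
  fp_caches <- vector("list", length(cfg$sa))
  below <- F
  for (l in rev(seq_along(cfg$sa))) {
    ip <- graph$fp[[l]]
    interp <- ip$w[, 1] * below[ip$idx[, 1], , drop = FALSE] +
      ip$w[, 2] * below[ip$idx[, 2], , drop = FALSE] +
      ip$w[, 3] * below[ip$idx[, 3], , drop = FALSE]
    X <- cbind(interp, feats[[l]])
    fwd <- mlp_fwd(net, sprintf("fp%d", l), X, train)
    fp_caches[[l]] <- list(fwd = fwd, n_below = nrow(below),
                           c_interp = ncol(below))
    below <- fwd$Y
  }
  h <- mlp_fwd(net, "head.hidden", cbind(below, features), train)
  dp <- dropout_fwd(h$Y, cfg$dropout, train, dropout_seed)
  o <- mlp_fwd(net, "head.out", dp$Y, train)
  logp <- log_softmax_rows(o$Y)
  list(logp = logp,
       cache = list(sa = sa_caches, fp = fp_caches, head_h = h, drop = dp,
                    head_o = o, logp = logp, graph = graph))
}

pm_seg_backward <- function(net, cache, dlogp) {
  dZ <- log_softmax_bwd(cache$logp, dlogp)
  dH <- mlp_bwd(net, "head.out", cache$head_o, dZ)
  if (!is.null(cache$drop$mask)) dH <- dH * cache$drop$mask
  dhin <- mlp_bwd(net, "head.hidden", cache$head_h, dH)
  cfg <- net$config
  dbelow <- dhin[, seq_len(cfg$fp_width[1]), drop = FALSE]
  L <- length(cfg$sa)
  # d_skip[[l]]: gradient w.r.t. feats[[l]] (input features for l = 1, SA
  # stage l-1 output otherwise); dbelow tracks the gradient w.r.t. the
  # feature tensor interpolated by the current FP stage.
  d_skip <- vector("list", L + 1L)
  for (l in seq_len(L)) {
    fpc <- cache$fp[[l]]
    dX <- mlp_bwd(net, sprintf("fp%d", l), fpc$fwd, dbelow)
    ci <- fpc$c_interp
    dinterp <- dX[, seq_len(ci), drop = FALSE]
    d_skip[[l]] <- add_or_set(d_skip[[l]], dX[, -seq_len(ci), drop = FALSE])
    ip <- cache$graph$fp[[l]]
    dbl <- matrix(0, fpc$n_below, ci)
    for (j in 1:3) {
      dbl <- dbl + scatter_rows(ip$w[, j] * dinterp, ip$idx[, j], fpc$n_below)
    }
    dbelow <- dbl  # grad w.r.t. FP output of stage l+1 (SA top output at l = L)
  }
  d_skip[[L + 1L]] <- add_or_set(d_skip[[L + 1L]], dbelow)
  for (l in rev(seq_len(L))) {
    dFin <- sa_stage_bwd(net, l, cache$sa[[l]], d_skip[[l + 1L]])
    d_skip[[l]] <- add_or_set(d_skip[[l]], dFin)
  }
  invisible(d_skip[[1]])
}

add_or_set <- function(a, b) if (is.null(a)) b else a + b

# Alignment forward: global feature -> FC -> raw 3x3 -> SVD projection.
pm_align_forward <- function(net, features, graph, train = FALSE) {
  cfg <- net$config
  F <- features
  sa_caches <- vector("list", length(cfg$sa))
  for (l in seq_along(cfg$sa)) {
    st <- sa_stage_fwd(net, l, graph, F, train)
    sa_caches[[l]] <- st
    F <- st$Y
  }
  P_top <- graph$levels[[length(cfg$sa) + 1L]]
  ctr <- colMeans(P_top)
  G <- cbind(sweep(P_top, 2, ctr), F)
  gf <- mlp_fwd(net, "global", G, train)
  mp <- maxpool_groups(gf$Y, 1L, nrow(gf$Y))
  fc <- mlp_fwd(net, "fc", mp$Y, train)
  Mraw <- matrix(as.numeric(fc$Y), 3, 3, byrow = TRUE)
  R <- pm_svd_project(Mraw)
  list(M = Mraw, R = R,
       cache = list(sa = sa_caches, gf = gf, argrow = mp$argrow, fc = fc,
                    n_top = nrow(gf$Y)))
}

pm_align_backward <- function(net, cache, dM) {
  dfc <- matrix(as.numeric(t(dM)), 1, 9)
  dglob <- mlp_bwd(net, "fc", cache$fc, dfc)
  dH <- cpp_maxpool_bwd(dglob, cache$argrow, cache$n_top)
  dG <- mlp_bwd(net, "global", cache$gf, dH)
  dF <- dG[, -(1:3), drop = FALSE]
  for (l in rev(seq_along(net$config$sa))) {
    dF <- sa_stage_bwd(net, l, cache$sa[[l]], dF)
  }
  invisible(dF)
}

check_min_points <- function(cloud, config) {
  deepest <- config$sa[[length(config$sa)]]$npoint
  if (pm_n_points(cloud) < deepest) {
    stop(sprintf("architecture constraint: cloud has %d points, deepest stage needs %d",
                 pm_n_points(cloud), deepest))
  }
}

#' Per-point class log-probabilities from a segmentation network
#'
#' Runs the network in evaluation mode (dropout off, running batch-norm
#' statistics). Each output row log-sum-exps to 0.
#'
#' @param net a `pm_seg_net`.
#' @param cloud a `pm_cloud` with the 6 feature channels of
#'   [pm_point_features()].
#' @param seed sampling seed for farthest-point selection.
#' @return N x C matrix of log-probabilities, row-aligned with the cloud.
#' @export
pm_segment_points <- function(net, cloud, seed = 1L) {
  if (is.null(cloud$features) || ncol(cloud$features) != 6L) {
    stop("cloud must carry the 6 feature channels (see pm_point_features)")
  }
  check_min_points(cloud, net$config)
  graph <- pm_build_graph(cloud$positions, net$config, seed)
  pm_seg_forward(net, cloud$features, graph, train = FALSE)$logp
}

#' Rotation prediction from an alignment network
#'
#' Evaluation-mode forward pass; the returned matrix is the SVD projection
#' of the regressed 9 values, hence always orthonormal with det +1.
#'
#' @param net a `pm_align_net`.
#' @param cloud a `pm_cloud` with 6 feature channels.
#' @param seed sampling seed.
#' @return A 3 x 3 rotation matrix.
#' @export
pm_predict_rotation <- function(net, cloud, seed = 1L) {
  if (is.null(cloud$features) || ncol(cloud$features) != 6L) {
    stop("cloud must carry the 6 feature channels (see pm_point_features)")
  }
  check_min_points(cloud, net$config)
  graph <- pm_build_graph(cloud$positions, net$config, seed)
  pm_align_forward(net, cloud$features, graph, train = FALSE)$R
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the configuration, all numeric state (weights and
#' batch-norm statistics) and a content hash of the configuration, so a
#' loaded model can be checked against the config it was trained with.
#'
#' @param net a `pm_seg_net` or `pm_align_net`.
#' @param path checkpoint file path (RDS container).
#' @return `path` invisibly; `pm_load_model` returns the restored network.
#' @export
pm_save_model <- function(net, path) {
  ck <- list(kind = net$kind, config = net$config, state = nn_state(net),
             config_hash = pm_config_hash(net$config))
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname pm_save_model
#' @export
pm_load_model <- function(path) {
  ck <- readRDS(path)
  net <- if (ck$kind == "seg") {
    n <- nn_new(); n$config <- ck$config; n$kind <- "seg"
    class(n) <- c("pm_seg_net", "environment"); n
  } else {
    n <- nn_new(); n$config <- ck$config; n$kind <- "align"
    class(n) <- c("pm_align_net", "environment"); n
  }
  nn_restore(net, ck$state)
  if (!identical(pm_config_hash(net$config), ck$config_hash)) {
    stop("checkpoint config hash mismatch")
  }
  net
}

#' Content hash of a model configuration
#' @param config a model configuration list.
#' @return Character md5 hash.
#' @export
pm_config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}
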
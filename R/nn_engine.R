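# Compact neural-network engine: shared (point-wise) MLPs with
# normalization and ReLU, manual backpropagation, Adam. Parameters live in a
# flat environment keyed by layer name, gradients in a parallel environment,
# so batch gradients accumulate across samples before each optimizer step.
# Normalization layers standardize each channel over the rows of the current
# forward pass (instance statistics) in both training and evaluation:
# samples are processed one cloud at a time, so per-forward statistics are
# the consistent choice and keep inference deterministic.

nn_new <- function() {
  net <- new.env(parent = emptyenv())
  net$par <- new.env(parent = emptyenv())   # trained parameters
  net$buf <- new.env(parent = emptyenv())   # layer metadata
  net$grad <- new.env(parent = emptyenv())  # accumulated gradients
  net$adam <- NULL
  net
}

nn_rnorm_mat <- function(n, m, sd, seed) {
  matrix(with_pm_seed(seed, stats::rnorm(n * m, 0, sd)), n, m)
}

# A shared MLP applied row-wise: for each layer, linear -> batchnorm -> ReLU.
# `bn_last`/`relu_last` control the final layer (regression outputs skip both).
mlp_init <- function(net, name, sizes, seed, bn = TRUE,
                     bn_last = bn, relu_last = TRUE) {
  L <- length(sizes) - 1L
  for (l in seq_len(L)) {
    nin <- sizes[l]; nout <- sizes[l + 1L]
    net$par[[paste0(name, ".W", l)]] <- nn_rnorm_mat(nin, nout, sqrt(2 / nin),
                                                     pm_child_seed(seed, l))
    net$par[[paste0(name, ".b", l)]] <- rep(0, nout)
    use_bn <- if (l == L) bn_last else bn
    if (use_bn) {
      net$par[[paste0(name, ".g", l)]] <- rep(1, nout)
      net$par[[paste0(name, ".be", l)]] <- rep(0, nout)
    }
  }
  meta <- list(name = name, L = L, sizes = sizes, bn = bn,
               bn_last = bn_last, relu_last = relu_last)
  net$par[[paste0(name, ".meta")]] <- NULL  # keep par purely numeric
  assign(paste0(name, ".meta"), meta, envir = net$buf)
  invisible(meta)
}

mlp_fwd <- function(net, name, X, train = TRUE) {
  meta <- get(paste0(name, ".meta"), envir = net$buf)
  caches <- vector("list", meta$L)
  for (l in seq_len(meta$L)) {
    W <- net$par[[paste0(name, ".W", l)]]
    b <- net$par[[paste0(name, ".b", l)]]
    use_bn <- if (l == meta$L) meta$bn_last else meta$bn
    use_relu <- l < meta$L || meta$relu_last
    g <- if (use_bn) net$par[[paste0(name, ".g", l)]] else numeric(ncol(W))
    be <- if (use_bn) net$par[[paste0(name, ".be", l)]] else numeric(ncol(W))
    r <- cpp_layer_fwd(X, W, b, g, be, use_bn, use_relu)
    caches[[l]] <- list(X = X, xc = r$xc, inv = r$inv, Y = r$Y,
                        use_bn = use_bn, relu = use_relu)
    X <- r$Y
  }
  list(Y = X, caches = caches)
}

grad_add <- function(net, key, val) {
  cur <- net$grad[[key]]
  net$grad[[key]] <- if (is.null(cur)) val else cur + val
}

mlp_bwd <- function(net, name, fwd, dY) {
  meta <- get(paste0(name, ".meta"), envir = net$buf)
  for (l in rev(seq_len(meta$L))) {
    cache <- fwd$caches[[l]]
    W <- net$par[[paste0(name, ".W", l)]]
    g <- if (cache$use_bn) net$par[[paste0(name, ".g", l)]] else numeric(ncol(W))
    r <- cpp_layer_bwd(dY, cache$X, W, g, cache$xc, cache$inv, cache$Y,
                       cache$use_bn, cache$relu)
    grad_add(net, paste0(name, ".W", l), r$dW)
    grad_add(net, paste0(name, ".b", l), as.numeric(r$db))
    if (cache$use_bn) {
      grad_add(net, paste0(name, ".g", l), as.numeric(r$dg))
      grad_add(net, paste0(name, ".be", l), as.numeric(r$dbe))
    }
    dY <- r$dX
  }
  dY
}

nn_zero_grad <- function(net) {
  rm(list = ls(net$grad), envir = net$grad)
  invisible(net)
}

nn_adam_init <- function(net, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, weight_decay = 0) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps; st$t <- 0L
  st$wd <- weight_decay
  st$m <- new.env(parent = emptyenv())
  st$v <- new.env(parent = emptyenv())
  net$adam <- st
  invisible(net)
}

nn_adam_step <- function(net, scale = 1) {
  st <- net$adam
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  bc1 <- 1 - b1^st$t
  bc2 <- 1 - b2^st$t
  for (key in ls(net$grad)) {
    g <- net$grad[[key]] * scale
    m <- st$m[[key]]; v <- st$v[[key]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    st$m[[key]] <- m
    st$v[[key]] <- v
    upd <- st$lr * (m / bc1) / (sqrt(v / bc2) + st$eps)
    if (st$wd > 0 && grepl("\\.W[0-9]+$", key)) {
      upd <- upd + st$lr * st$wd * net$par[[key]]  # decoupled decay, weights only
    }
    net$par[[key]] <- net$par[[key]] - upd
  }
  invisible(net)
}

# log-softmax over rows, with backward
log_softmax_rows <- function(Z) {
  mx <- apply(Z, 1, max)
  Zs <- Z - mx
  Zs - log(rowSums(exp(Zs)))
}

log_softmax_bwd <- function(logP, dlogP) {
  dlogP - exp(logP) * rowSums(dlogP)
}

dropout_fwd <- function(X, p, train, seed) {
  if (!train || p <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix(with_pm_seed(seed, stats::runif(length(X))) >= p,
                 nrow(X), ncol(X)) / (1 - p)
  list(Y = X * mask, mask = mask)
}

# serialize / restore all numeric state (used by checkpoint save/load)
nn_state <- function(net) {
  bufl <- as.list(net$buf)
  is_meta <- grepl("\\.meta$", names(bufl))
  list(par = as.list(net$par), buf = bufl[!is_meta], meta = bufl[is_meta])
}

nn_restore <- function(net, state) {
  for (k in names(state$par)) net$par[[k]] <- state$par[[k]]
  for (k in names(state$buf)) net$buf[[k]] <- state$buf[[k]]
  for (k in names(state$meta)) assign(k, state$meta[[k]], envir = net$buf)
  invisible(net)
}
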
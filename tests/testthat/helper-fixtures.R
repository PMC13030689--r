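# shared fixtures: random rotations, small clouds, landmark sets

random_rotation <- function(seed) {
  set.seed(seed)
  pm_svd_project(matrix(rnorm(9), 3, 3))
}

random_cloud <- function(n, seed, range = 100) {
  set.seed(seed)
  pm_cloud(matrix(runif(n * 3, -range, range), n, 3))
}

random_landmarks <- function(seed, spread = 150) {
  set.seed(seed)
  m <- matrix(runif(18, -spread, spread), 6, 3)
  rownames(m) <- pm_landmark_names()
  pm_landmarks(m)
}

# a small, well-separated landmark configuration in canonical pose
canonical_landmarks <- function(dy = 0) {
  pm_landmarks(list(
    PSIS_L = c(-45, dy, 0), PSIS_R = c(45, -dy, 0),
    IC_L = c(-130, 45, -12), IC_R = c(130, 45, -12),
    L1 = c(0, 215, 8), L4 = c(2, 65, 0)))
}

# tiny scan set shared across training-oriented tests (cheap to build)
tiny_scans <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- pm_generate_dataset(6, visits = 1, repeats_per_visit = 2,
                                    seed = 401, n_points = 12000)
    }
    cache
  }
})

# very small network configs so forward/backward tests stay fast
mini_seg_config <- function(n_classes = 2L, dropout = 0.5) {
  cfg <- pm_seg_config("tiny", n_classes = n_classes, dropout = dropout)
  cfg$sa <- list(
    list(npoint = 32L, radius = 80, K = 8L, mlp = list(c(16, 16))),
    list(npoint = 8L, radius = 240, K = 4L, mlp = list(c(16, 32))))
  cfg$fp_width <- c(16, 16)
  cfg$head <- 16
  cfg
}

mini_align_config <- function() {
  cfg <- pm_align_config("tiny")
  cfg$sa <- list(
    list(npoint = 32L, radius = 100, K = 8L, mlp = list(c(16, 16))),
    list(npoint = 8L, radius = 300, K = 4L, mlp = list(c(16, 32))))
  cfg$global_mlp <- c(32, 32)
  cfg$fc <- c(16)
  cfg
}
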
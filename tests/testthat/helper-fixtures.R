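# Small phantom configuration for fast unit tests; the full-size default
# configuration is exercised in the acceptance suite.
small_config <- function(...) {
  phantom_config(dim = c(32L, 32L, 20L), spacing = c(2, 2, 3),
                 n_texture = 20L, ...)
}

# cache the default small case across tests within one run
small_case <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom_case(small_config(seed = 42L))
    cache
  }
})

# a smooth random volume with reproducible content
toy_volume <- function(dims = c(10, 9, 8), spacing = c(2, 2, 3), seed = 1) {
  set.seed(seed)
  x <- array(rnorm(prod(dims)), dims)
  # mild smoothing so gradients are informative
  sm <- (x +
    x[c(1, seq_len(dims[1] - 1)), , ] + x[c(seq_len(dims[1] - 1) + 1, dims[1]), , ] +
    x[, c(1, seq_len(dims[2] - 1)), ] + x[, c(seq_len(dims[2] - 1) + 1, dims[2]), ] +
    x[, , c(1, seq_len(dims[3] - 1))] + x[, , c(seq_len(dims[3] - 1) + 1, dims[3])]) / 7
  new_volume(sm, make_affine(spacing))
}

# small landmark table with two annotators
toy_landmarks <- function() {
  data.frame(
    case_id = "case01", pair_id = "p1",
    landmark_id = rep(c("lm01", "lm02", "lm03"), each = 2),
    fx = rep(c(10, 20, 30), each = 2), fy = rep(c(12, 22, 32), each = 2),
    fz = rep(c(9, 15, 21), each = 2),
    annotator_id = rep(c("A1", "A2"), 3),
    mx = c(10, 10, 21, 23, 30, 30), my = c(12, 12, 22, 22, 33, 36),
    mz = c(9, 9, 15, 15, 21, 21),
    uncertain = FALSE, stringsAsFactors = FALSE)
}

# brute-force curvature energy: independent finite-difference oracle
oracle_curvature <- function(field) {
  d <- field$dim
  h <- field$spacing
  voxvol <- abs(det(field$affine[1:3, 1:3]))
  total <- 0
  for (l in 1:3) {
    u <- field$u[, , , l]
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      lap <- 0
      if (i > 1 && i < d[1])
        lap <- lap + (u[i - 1, j, k] - 2 * u[i, j, k] + u[i + 1, j, k]) / h[1]^2
      if (j > 1 && j < d[2])
        lap <- lap + (u[i, j - 1, k] - 2 * u[i, j, k] + u[i, j + 1, k]) / h[2]^2
      if (k > 1 && k < d[3])
        lap <- lap + (u[i, j, k - 1] - 2 * u[i, j, k] + u[i, j, k + 1]) / h[3]^2
      total <- total + lap^2
    }
  }
  0.5 * voxvol * total
}

# brute-force folding detector: signed tetrahedron volumes in world
# coordinates over every cell corner, fully independent of the compiled path
oracle_foldings <- function(field) {
  d <- field$dim
  A <- field$affine
  pos <- function(i, j, k) { # world position of deformed node (0-based ijk)
    w <- A[1:3, 1:3] %*% c(i, j, k) + A[1:3, 4]
    w + field$u[i + 1, j + 1, k + 1, ]
  }
  ref_sign <- sign(det(A[1:3, 1:3]))
  count <- 0
  for (k in 0:(d[3] - 2)) for (j in 0:(d[2] - 2)) for (i in 0:(d[1] - 2)) {
    for (c in 0:7) {
      di <- bitwAnd(c, 1L); dj <- bitwAnd(bitwShiftR(c, 1L), 1L)
      dk <- bitwAnd(bitwShiftR(c, 2L), 1L)
      corner <- c(i + di, j + dj, k + dk)
      pc <- pos(corner[1], corner[2], corner[3])
      adj <- list(c(1 - di, dj, dk), c(di, 1 - dj, dk), c(di, dj, 1 - dk))
      M <- sapply(adj, function(a) pos(i + a[1], j + a[2], k + a[3]) - pc)
      s <- det(M)
      parity <- if ((di + dj + dk) %% 2 == 0) 1 else -1
      ref <- parity * ref_sign
      if (s == 0 || sign(s) != ref) count <- count + 1
    }
  }
  count
}
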
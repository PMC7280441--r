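# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small template-resolution atlas (32^3, 4 mm) for cheap pipeline tests.
small_spec <- function(...) {
  phantom_spec(grid_shape = 32L, subject_factor = 1L, seed = 202L, ...)
}

small_atlas <- function() {
  cached("small_atlas", function() make_atlas_phantom(small_spec()))
}

# Mid-resolution atlas (48^3) used by registration-quality tests.
mid_spec <- function(...) phantom_spec(grid_shape = 48L, seed = 303L, ...)

mid_atlas <- function() {
  cached("mid_atlas", function() make_atlas_phantom(mid_spec()))
}

default_profile <- function() {
  cached("default_profile", function() group_uptake_profile())
}

# Random small binary mask on a shared grid (for metric tests).
random_mask <- function(grid, p = 0.2, connected = FALSE) {
  m <- array(stats::runif(prod(grid$shape)) < p, dim = grid$shape)
  if (connected) {
    # A random ball, guaranteed nonempty.
    ctr <- stats::runif(3, 2, grid$shape - 3)
    idx <- as.matrix(expand.grid(seq_len(grid$shape[1]) - 1,
                                 seq_len(grid$shape[2]) - 1,
                                 seq_len(grid$shape[3]) - 1))
    r <- stats::runif(1, 1.5, min(grid$shape) / 3)
    m <- array(sqrt(colSums((t(idx) - ctr)^2)) <= r, dim = grid$shape)
  }
  binary_mask(m, grid)
}

# Independent all-pairs Hausdorff oracle (plain loops over full masks).
brute_hausdorff <- function(a, b) {
  A <- which(a$membership, arr.ind = TRUE) - 1
  B <- which(b$membership, arr.ind = TRUE) - 1
  dmat <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    dmat[i, ] <- sqrt((A[i, 1] - B[, 1])^2 + (A[i, 2] - B[, 2])^2 +
                        (A[i, 3] - B[, 3])^2)
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# Independent Dice oracle by explicit voxel scan.
brute_dice <- function(a, b) {
  inter <- 0L; na <- 0L; nb <- 0L
  av <- as.vector(a$membership); bv <- as.vector(b$membership)
  for (i in seq_along(av)) {
    if (av[i]) na <- na + 1L
    if (bv[i]) nb <- nb + 1L
    if (av[i] && bv[i]) inter <- inter + 1L
  }
  2 * inter / (na + nb)
}

# Smooth random deformation field for algebra tests (amplitude in
# voxels of the grid).
random_test_field <- function(grid, amplitude_vox = 2, smooth_vox = 3,
                              direction = "forward", taper = TRUE,
                              margin = max(3, 2 * amplitude_vox)) {
  amp_mm <- amplitude_vox * min(grid$spacing)
  comps <- lapply(1:3, function(k)
    neuroquant:::gaussian_smooth(array(stats::rnorm(prod(grid$shape)),
                                       dim = grid$shape), smooth_vox))
  mag <- sqrt(comps[[1]]^2 + comps[[2]]^2 + comps[[3]]^2)
  comps <- lapply(comps, function(a) a * amp_mm / max(mag))
  if (taper) {
    # fade to zero near the domain boundary so the field maps the
    # bounded domain into itself (well-posed inversion); the ramp is
    # wide enough to keep the Jacobian perturbation below ~0.5
    w1 <- function(n) {
      u <- pmin(1, pmin(seq_len(n) - 1, n - seq_len(n)) / margin)
      0.5 * (1 - cos(pi * u))  # kink-free raised-cosine ramp
    }
    s <- grid$shape
    w <- outer(outer(w1(s[1]), w1(s[2])), w1(s[3]))
    dim(w) <- s
    comps <- lapply(comps, function(a) a * w)
  }
  deformation_field(comps, grid, direction = direction)
}
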
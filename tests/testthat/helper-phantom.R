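# Small phantom used across tests: same spacing and proportions as the
# default, scaled down so suites stay fast.
small_spec <- function(...) {
  phantom_spec(grid_shape = c(96, 80, 24), liver_semiaxes_mm = c(28, 22, 24),
               ...)
}

# mid-size phantom for estimator-bias simulations
bias_spec <- function(seed, ...) {
  phantom_spec(grid_shape = c(128, 112, 30), liver_semiaxes_mm = c(40, 32, 30),
               seed = seed, ...)
}

# axis-aligned cuboid mask on a small grid
cube_mask <- function(i, j, k, dim = c(8, 8, 8), spacing = c(1, 1, 1)) {
  arr <- array(FALSE, dim = dim)
  arr[i, j, k] <- TRUE
  binary_mask(arr, spacing_mm = spacing)
}

# random blobby mask: union of a few random balls, possibly empty-checked
random_mask <- function(dim = c(14, 14, 10), spacing = c(0.7, 0.7, 2.5),
                        n_balls = 3) {
  arr <- array(FALSE, dim = dim)
  x <- (seq_len(dim[1]) - 1) * spacing[1]
  y <- (seq_len(dim[2]) - 1) * spacing[2]
  z <- (seq_len(dim[3]) - 1) * spacing[3]
  for (b in seq_len(n_balls)) {
    c0 <- c(runif(1, min(x), max(x)), runif(1, min(y), max(y)),
            runif(1, min(z), max(z)))
    r <- runif(1, 1.5, 5)
    d2 <- outer(outer((x - c0[1])^2, (y - c0[2])^2, `+`), (z - c0[3])^2, `+`)
    arr <- arr | (d2 <= r^2)
  }
  if (!any(arr)) arr[ceiling(dim[1] / 2), ceiling(dim[2] / 2),
                     ceiling(dim[3] / 2)] <- TRUE
  binary_mask(arr, spacing_mm = spacing)
}
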
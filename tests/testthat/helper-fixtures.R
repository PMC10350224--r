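# Small-sensor fixtures used across tests: full-frame (2048-row) objects are
# only needed where a printed instrument quantity is being checked.

small_scaling <- function(n_rows = 64L, n_cols = 64L)
  immersion_scaling(n_rows = n_rows, n_cols = n_cols)

small_cam <- function(mode = "single", n_rows = 64L, n_cols = 64L,
                      shutter_width = 16L, ...)
  camera_config(n_rows = n_rows, n_cols = n_cols,
                shutter_width = shutter_width, mode = mode, ...)

# Noise-free synthetic Gaussian bead stack with background floor.
gaussian_bead_stack <- function(dims, center, sigma, amplitude = 1000,
                                floor = 100) {
  g1 <- function(n, c0, s) exp(-(seq_len(n) - c0)^2 / (2 * s^2))
  floor + amplitude *
    (outer(g1(dims[1], center[1], sigma[1]),
           g1(dims[2], center[2], sigma[2])) %o%
       g1(dims[3], center[3], sigma[3]))
}

# Normalized 3D Gaussian kernel.
gaussian_psf <- function(dims, sigma) {
  g1 <- function(n, s) { x <- seq_len(n) - (n + 1) / 2; exp(-x^2 / (2 * s^2)) }
  k <- outer(g1(dims[1], sigma[1]), g1(dims[2], sigma[2])) %o%
    g1(dims[3], sigma[3])
  k / sum(k)
}

# Brute-force mean box filter matching the package conventions (even kernel
# origin toward the lower index, edge-duplicating reflective padding);
# written independently of the summed-area-table implementation.
brute_box_smooth <- function(img, k) {
  lo <- k %/% 2L
  hi <- k - 1L - lo
  nr <- nrow(img); nc <- ncol(img)
  reflect <- function(i, n) {
    i[i < 1] <- 1 - i[i < 1]
    i[i > n] <- 2 * n + 1 - i[i > n]
    i
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    ri <- reflect((i - lo):(i + hi), nr)
    for (j in seq_len(nc)) {
      cj <- reflect((j - lo):(j + hi), nc)
      out[i, j] <- mean(img[ri, cj])
    }
  }
  out
}

brute_intensity_score <- function(m, params) {
  d <- brute_box_smooth(m, params$kernel_small) -
    brute_box_smooth(m, params$kernel_large)
  100 * sum(d > params$intensity_threshold) / length(d)
}
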
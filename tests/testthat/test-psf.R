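test_that("MIP equals the brute-force projection along every axis", {
  set.seed(21)
  x <- array(rnorm(7 * 6 * 5), dim = c(7, 6, 5))
  for (axis in 1:3) {
    got <- mip(x, axis)
    keep <- setdiff(1:3, axis)
    ref <- matrix(0, dim(x)[keep[1]], dim(x)[keep[2]])
    for (i in seq_len(nrow(ref))) for (j in seq_len(ncol(ref))) {
      idx <- rep(list(TRUE), 3)
      idx[[keep[1]]] <- i; idx[[keep[2]]] <- j
      ref[i, j] <- max(x[idx[[1]], idx[[2]], idx[[3]]])
    }
    expect_equal(got, ref)
  }
  expect_error(mip(array(1, c(2, 2)), 3), "3D")
})

test_that("bead detection finds separated peaks and rejects noise", {
  empty <- array(0, c(20, 20, 10))
  expect_identical(nrow(detect_beads(empty, threshold = 1)), 0L)
  two <- gaussian_bead_stack(c(48, 24, 16), c(12, 12, 8), c(1.5, 1.5, 1.5)) +
    gaussian_bead_stack(c(48, 24, 16), c(32, 12, 8), c(1.5, 1.5, 1.5)) - 100
  det <- detect_beads(two, threshold = 500, min_separation = 5)
  expect_identical(nrow(det), 2L)
  expect_true(all(sort(det$row) == c(12, 32)))
  # a single bead's integer peak is within one voxel of the true centre
  one <- gaussian_bead_stack(c(24, 24, 16), c(10.4, 13.7, 7.2), c(2, 2, 2))
  d1 <- detect_beads(one, threshold = 500, min_separation = 3)
  expect_true(all(abs(c(d1$row[1], d1$col[1], d1$plane[1]) -
                        c(10.4, 13.7, 7.2)) <= 1))
})

test_that("FWHM of a synthetic Gaussian bead is 2.3548 sigma voxel", {
  st <- gaussian_bead_stack(c(33, 33, 33), c(17, 17, 17), c(2, 2, 2))
  m <- bead_fwhm(st, c(17, 17, 17), voxel_size = 0.2)
  expect_true(m$ok)
  expect_equal(unname(m$fwhm), rep(2 * sqrt(2 * log(2)) * 2 * 0.2, 3),
               tolerance = 0.01)
  expect_gt(m$fit_quality, 0.99)
})

test_that("FWHM estimator bias is small, noise-free and under Poisson noise", {
  for (sig in c(1.5, 2, 3)) {
    st <- gaussian_bead_stack(c(33, 33, 33), c(17, 17, 17), rep(sig, 3),
                              amplitude = 1000)
    m <- bead_fwhm(st, c(17, 17, 17), voxel_size = 1)
    truth <- 2 * sqrt(2 * log(2)) * sig
    expect_lt(abs(m$fwhm[["y"]] - truth) / truth, 0.01)
  }
  # Poisson noise at peak 100 counts above background
  set.seed(31)
  clean <- gaussian_bead_stack(c(33, 33, 33), c(17, 17, 17), c(2, 2, 2),
                               amplitude = 100, floor = 20)
  noisy <- array(rpois(length(clean), clean), dim = dim(clean))
  m <- bead_fwhm(noisy, c(17, 17, 17), voxel_size = 1)
  truth <- 2 * sqrt(2 * log(2)) * 2
  expect_lt(abs(m$fwhm[["y"]] - truth) / truth, 0.05)
  expect_lt(abs(m$fwhm[["z"]] - truth) / truth, 0.05)
})

test_that("refractive-index conversion of widths is multiplicative n1/n2", {
  expect_equal(round(convert_fwhm(0.97, 1.33, 1.56), 2), 0.83)
  expect_identical(convert_fwhm(1.2, 1.4, 1.4), 1.2)
  expect_equal(convert_fwhm(convert_fwhm(0.97, 1.33, 1.56), 1.56, 1.33),
               0.97, tolerance = 1e-12)
})

test_that("Richardson-Lucy with a delta PSF is the identity", {
  set.seed(41)
  x <- array(runif(16^3, 10, 200), dim = c(16, 16, 16))
  delta <- array(0, c(3, 3, 3)); delta[2, 2, 2] <- 1
  expect_equal(richardson_lucy(x, delta, 5), x, tolerance = 1e-8)
})

test_that("Richardson-Lucy sharpens monotonically and conserves flux", {
  psf <- gaussian_psf(c(9, 9, 9), c(1.5, 1.5, 1.5))
  blur <- gaussian_bead_stack(c(33, 33, 33), c(17, 17, 17), c(1.5, 1.5, 1.5),
                              amplitude = 1000, floor = 0)
  fwhms <- numeric(10)
  est <- blur
  for (it in 1:10) {
    est <- richardson_lucy(blur, psf, it)
    fwhms[it] <- bead_fwhm(est, c(17, 17, 17), voxel_size = 1)$fwhm[["y"]]
  }
  input_fwhm <- bead_fwhm(blur, c(17, 17, 17), voxel_size = 1)$fwhm[["y"]]
  expect_true(all(fwhms < input_fwhm))
  expect_true(all(diff(fwhms) <= 1e-6))
  expect_equal(sum(richardson_lucy(blur, psf, 10)) / sum(blur), 1,
               tolerance = 0.01)
  expect_error(richardson_lucy(blur, psf * 0, 5), "normalizable")
})

test_that("SNR follows the (fg - bg)/sd_bg definition", {
  x <- array(0, c(3, 3, 1))
  x[, 1, 1] <- 300                   # foreground, constant
  x[, 2, 1] <- c(90, 100, 110)       # background, mean 100, sd exactly 10
  fg <- array(FALSE, dim(x)); fg[, 1, 1] <- TRUE
  bg <- array(FALSE, dim(x)); bg[, 2, 1] <- TRUE
  r <- snr(x, fg, bg)
  expect_equal(r$snr, 20)
  # homogeneity: tripling the foreground excess triples the snr ...
  x2 <- x
  x2[fg] <- (x2[fg] - 100) * 3 + 100
  expect_equal(snr(x2, fg, bg)$snr, 3 * r$snr)
  # ... while rescaling the whole image (offset removed) leaves it unchanged
  expect_equal(snr((x - 100) * 3, fg, bg)$snr, r$snr)
  # identical statistics give snr ~ 0
  set.seed(51)
  y <- array(rnorm(1000, 100, 5), c(10, 10, 10))
  fg2 <- array(FALSE, dim(y)); fg2[1:5, , ] <- TRUE
  bg2 <- array(FALSE, dim(y)); bg2[6:10, , ] <- TRUE
  expect_lt(abs(snr(y, fg2, bg2)$snr), 0.5)
  expect_error(snr(y, fg2, fg2), "disjoint")
  expect_error(snr(array(100, c(2, 2, 1)),
                   array(c(TRUE, FALSE, FALSE, FALSE), c(2, 2, 1)),
                   array(c(FALSE, TRUE, TRUE, FALSE), c(2, 2, 1))),
               "zero")
})

test_that("measure_beads summarizes only successful fits", {
  st <- gaussian_bead_stack(c(40, 40, 20), c(12, 12, 10), c(2, 2, 2)) +
    gaussian_bead_stack(c(40, 40, 20), c(30, 30, 10), c(2, 2, 2)) - 100
  f <- tempfile(fileext = ".csv")
  tab <- measure_beads(st, threshold = 500, min_separation = 5,
                       voxel_size = 0.4, file = f)
  expect_identical(nrow(tab), 2L)
  expect_true(all(tab$ok))
  expect_true(file.exists(f))
  expect_equal(tab$fwhm_y, rep(2 * sqrt(2 * log(2)) * 2 * 0.4, 2),
               tolerance = 0.02)
})
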
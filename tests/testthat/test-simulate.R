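# Shared small-scene fixtures for image-formation tests.
sim_scene <- function(mode = "single", n_rows = 48L, n_frames = 24L,
                      frame_time = 0.1, n_beads = 1L, intensity = 2e5,
                      seed = 2) {
  sc <- small_scaling(n_rows = n_rows, n_cols = n_rows)
  p <- pixel_size(sc, 1.33)
  ph <- bead_phantom(c(n_rows, n_rows, n_frames) * p, n_beads,
                     intensity = intensity, seed = seed)
  cam <- small_cam(mode = mode, n_rows = n_rows, n_cols = n_rows,
                   shutter_width = 8L)
  w <- drive_waveform(mode, frame_time, n_frames = n_frames, scaling = sc)
  list(sc = sc, p = p, ph = ph, cam = cam, w = w)
}

test_that("an emitter-free phantom produces offset plus read noise", {
  s <- sim_scene(n_beads = 0L)
  st <- simulate_stack(s$ph, beam_parameters(), s$sc, s$cam, s$w, seed = 1)
  expect_equal(mean(st$counts), 100, tolerance = 0.1)
  expect_equal(sd(st$counts), 2, tolerance = 0.3)
})

test_that("stacks are reproducible for a fixed seed", {
  s <- sim_scene()
  a <- simulate_stack(s$ph, beam_parameters(), s$sc, s$cam, s$w, seed = 9)
  b <- simulate_stack(s$ph, beam_parameters(), s$sc, s$cam, s$w, seed = 9)
  expect_identical(a$counts, b$counts)
  c2 <- simulate_stack(s$ph, beam_parameters(), s$sc, s$cam, s$w, seed = 10)
  expect_false(identical(a$counts, c2$counts))
})

test_that("imaged bead FWHM is the quadrature of sheet and detection widths", {
  s <- sim_scene(intensity = 2e6)
  beam <- beam_parameters()
  st <- simulate_stack(s$ph, beam, s$sc, s$cam, s$w, seed = 3)
  det <- detect_beads(st, threshold = 5000, min_separation = 5)
  expect_identical(nrow(det), 1L)
  m <- bead_fwhm(st, c(det$row[1], det$col[1], det$plane[1]))
  sig_bead <- s$ph$diameter / 4
  fwhm_lat <- sqrt(0.92^2 + (2 * sqrt(2 * log(2)) * sig_bead)^2)
  sig_sheet <- beam$waist_radius / 2
  fwhm_ax <- sqrt(0.71^2 + (2 * sqrt(2 * log(2)))^2 *
                    (sig_sheet^2 + sig_bead^2))
  expect_equal(m$fwhm[["x"]], fwhm_lat, tolerance = 0.03)
  expect_equal(m$fwhm[["y"]], fwhm_lat, tolerance = 0.03)
  expect_equal(m$fwhm[["z"]], fwhm_ax, tolerance = 0.03)
})

test_that("dual mode doubles the integrated bead signal at equal T and W", {
  sS <- sim_scene(mode = "single", frame_time = 0.1)
  sD <- sim_scene(mode = "dual", frame_time = 0.1)
  stS <- simulate_stack(sS$ph, beam_parameters(), sS$sc, sS$cam, sS$w,
                        seed = 5)
  stD <- simulate_stack(sD$ph, beam_parameters(), sD$sc, sD$cam, sD$w,
                        seed = 6)
  bg <- 100
  sig <- function(st) sum(as.numeric(st$counts)) - bg * length(st$counts)
  expect_equal(sig(stD) / sig(stS), 2, tolerance = 0.03)
})

test_that("axial FWHM degrades monotonically with synchronization error", {
  s <- sim_scene(intensity = 2e6)
  beam <- beam_parameters()
  w0 <- beam$waist_radius
  fwhms <- vapply(c(0, 1, 2, 4) * w0, function(delta) {
    st <- simulate_stack(s$ph, beam, s$sc, s$cam, s$w, seed = 4,
                         sync_offset = delta)
    det <- detect_beads(st, threshold = 5000, min_separation = 5)
    bead_fwhm(st, c(det$row[1], det$col[1], det$plane[1]))$fwhm[["z"]]
  }, numeric(1))
  expect_true(all(diff(fwhms) > 0))
})

test_that("saturated voxels are clipped with a warning", {
  s <- sim_scene(intensity = 5e9)
  expect_warning(
    st <- simulate_stack(s$ph, beam_parameters(), s$sc, s$cam, s$w, seed = 7),
    "saturated")
  expect_lte(max(st$counts), 65535L)
})

test_that("SNR ratio model has the correct analytic limits", {
  # shot-noise limit at half the exposure: 1/sqrt(2)
  expect_equal(snr_ratio_model(1e5, 0, 0, 0.00625, 0.0125), 1 / sqrt(2))
  # read-noise-dominated limit: ratio of exposures
  expect_equal(snr_ratio_model(1e-3, 1e-3, 100, 0.00625, 0.0125), 0.5,
               tolerance = 1e-6)
  expect_equal(snr_ratio_model(1e4, 50, 2, 0.02, 0.02), 1)
  expect_error(snr_ratio_model(0, 0, 0, 0.01, 0.02), "zero")
})

test_that("predicted dual/single SNR ratio stays within the model bounds", {
  # across noise regimes the 25 ms dual vs 100 ms single ratio lies in
  # [exposure ratio, sqrt(exposure ratio)] = [0.5, 0.7071]
  e_dual <- 256 * 0.025 / 1024
  e_single <- 256 * 0.1 / 2048
  for (S in c(1e2, 1e4, 1e6)) for (B in c(0, 1e3)) for (r in c(0, 2, 50)) {
    if (S * e_single + B * e_single + r^2 == 0) next
    ratio <- snr_ratio_model(S, B, r, e_dual, e_single)
    expect_gte(ratio, 0.5 - 1e-12)
    expect_lte(ratio, 1 / sqrt(2) + 1e-12)
  }
})
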
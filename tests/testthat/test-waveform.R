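test_that("sawtooth waveform has one trigger per period and resets", {
  w <- drive_waveform("dual", frame_time = 0.025, flyback_time = 0.0025,
                      n_frames = 10L)
  expect_length(w$trigger_times, 10L)
  expect_equal(w$period, 0.0275)
  expect_equal(diff(w$trigger_times), rep(0.0275, 9))
  # position returns to start each period: command at period starts is 0
  starts <- sapply(w$trigger_times,
                   function(t0) w$command[which.min(abs(w$time - t0))])
  expect_equal(starts, rep(0, 10))
  # net commanded displacement over one full period is zero
  i0 <- which.min(abs(w$time - w$period))
  expect_equal(w$command[i0] - w$command[1], 0)
})

test_that("default amplitude is the FOV in single mode and half in dual", {
  ws <- drive_waveform("single", frame_time = 0.1)
  wd <- drive_waveform("dual", frame_time = 0.025)
  sc <- immersion_scaling()
  expect_equal(ws$amplitude, field_of_view(sc, 1.33))
  expect_equal(wd$amplitude, field_of_view(sc, 1.33) / 2)
})

test_that("laser is gated off during flyback", {
  w <- drive_waveform("single", frame_time = 0.01, flyback_time = 0.002,
                      n_frames = 3L)
  t_in <- w$time %% w$period
  in_fly <- t_in >= w$frame_time & w$time < 3 * w$period
  expect_false(any(w$laser_gate[in_fly]))
  expect_true(all(w$laser_gate[t_in < w$frame_time & w$time < 3 * w$period]))
})

test_that("insufficient sample rate is rejected", {
  expect_error(drive_waveform("single", 0.1, sample_rate = 5), "sample_rate")
})

test_that("an idealized actuator tracks the command exactly", {
  w <- drive_waveform("dual", 0.025, n_frames = 5L)
  tr <- lfa_track(w, lfa_model(response_time = 0))
  expect_equal(max(abs(tr$error)), 0)
})

test_that("slower sweeps reduce the rise-phase tracking error", {
  lfa <- lfa_model()
  A <- 400
  errs <- vapply(c(0.025, 0.05, 0.1, 0.2), function(T)
    lfa_track(drive_waveform("single", T, amplitude = A, n_frames = 3L),
              lfa)$max_rise_error, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
  expect_true(errs[length(errs)] < errs[1])
})

test_that("tracking error is linear in the sweep amplitude", {
  lfa <- lfa_model()
  e1 <- lfa_track(drive_waveform("single", 0.05, amplitude = 400,
                                 n_frames = 3L), lfa)$max_rise_error
  e2 <- lfa_track(drive_waveform("single", 0.05, amplitude = 200,
                                 n_frames = 3L), lfa)$max_rise_error
  expect_equal(e1 / e2, 2, tolerance = 1e-9)
})

test_that("synchronization offsets vanish for an ideal actuator", {
  for (mode in c("single", "dual")) {
    cam <- small_cam(mode = mode, shutter_width = 8L)
    w <- drive_waveform(mode, 0.05, n_frames = 2L,
                        scaling = small_scaling())
    off <- synchronization_map(w, lfa_model(response_time = 0), cam)
    expect_equal(off, rep(0, cam$n_rows))
  }
})

test_that("a pure transport lag offsets interior rows by slope x lag", {
  cam <- small_cam(mode = "single", shutter_width = 4L)
  w <- drive_waveform("single", 0.05, n_frames = 2L,
                      scaling = small_scaling())
  lag <- 4e-4
  off <- synchronization_map(w, lfa_model(response_time = 0, lag = lag), cam)
  slope <- w$amplitude / w$frame_time
  interior <- 5:50  # rows whose exposure midpoint lies inside the rise
  expect_equal(off[interior], rep(-slope * lag, length(interior)),
               tolerance = 1e-6)
})

test_that("dual-mode paired rows have identical synchronization offsets", {
  cam <- small_cam(mode = "dual", n_rows = 64L, shutter_width = 8L)
  w <- drive_waveform("dual", 0.05, n_frames = 2L, scaling = small_scaling())
  off <- synchronization_map(w, lfa_model(), cam)
  expect_equal(off[1:32], off[33:64])
})

test_that("waveform/camera mode mismatch is rejected", {
  w <- drive_waveform("single", 0.05, scaling = small_scaling())
  expect_error(synchronization_map(w, lfa_model(), small_cam(mode = "dual")),
               "disagree")
})

test_that("waveform CSV export round-trips the sampled command", {
  w <- drive_waveform("dual", 0.02, n_frames = 2L)
  f <- tempfile(fileext = ".csv")
  write_waveform_csv(w, f)
  df <- read.csv(f)
  expect_equal(df$command_um, w$command)
  expect_identical(sum(df$trigger), 2L)
})
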
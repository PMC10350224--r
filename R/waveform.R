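#' Sawtooth actuator drive waveform
#'
#' One acquisition cycle drives the focus actuator linearly over the sweep
#' range during the frame (rise) time `frame_time`, then returns it to the
#' start during the flyback (settle) time. The camera is triggered once at the
#' start of each period and the laser is gated off during flyback. In dual
#' mode the two foci each cover half the field of view, so the sweep
#' amplitude is half that of single mode.
#'
#' @param mode `"single"` or `"dual"`.
#' @param frame_time Rise/sweep time T per frame, seconds (this is the
#'   per-frame acquisition time, pfAT).
#' @param flyback_time Actuator return time F per frame, seconds. Defaults to
#'   10% of `frame_time`.
#' @param n_frames Number of frames (periods).
#' @param sample_rate Waveform sample rate, Hz. Defaults to 100 samples over
#'   the shortest phase.
#' @param amplitude Sweep amplitude in sample micrometres. Defaults to the
#'   field of view at index `n` for single mode and half of it for dual mode.
#' @param scaling,n Used only to derive the default amplitude.
#' @return An object of class `drive_waveform`: time grid `time`, commanded
#'   position `command` (µm), logical `laser_gate`, `trigger_times`, plus the
#'   scalar parameters.
#' @examples
#' w <- drive_waveform("dual", frame_time = 0.025, n_frames = 10)
#' length(w$trigger_times)  # 10
#' @export
drive_waveform <- function(mode = c("single", "dual"),
                           frame_time,
                           flyback_time = 0.1 * frame_time,
                           n_frames = 1L,
                           sample_rate = NULL,
                           amplitude = NULL,
                           scaling = immersion_scaling(),
                           n = 1.33) {
  mode <- match.arg(mode)
  chk_num(frame_time, "frame_time", lower = 0, strict_lower = TRUE)
  chk_num(flyback_time, "flyback_time", lower = 0)
  n_frames <- chk_count(n_frames, "n_frames")
  if (is.null(amplitude)) {
    fov <- field_of_view(scaling, n)
    amplitude <- if (mode == "dual") fov / 2 else fov
  }
  chk_num(amplitude, "amplitude", lower = 0, strict_lower = TRUE)
  shortest <- if (flyback_time > 0) min(frame_time, flyback_time) else frame_time
  if (is.null(sample_rate)) sample_rate <- 100 / shortest
  chk_num(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  if (sample_rate < 10 / shortest)
    stop("sample_rate too low to resolve the waveform (need >= 10 samples ",
         "over the shortest phase)", call. = FALSE)

  period <- frame_time + flyback_time
  t_end <- n_frames * period
  time <- seq(0, t_end, by = 1 / sample_rate)
  t_in <- time %% period
  in_rise <- t_in < frame_time & time < t_end
  command <- numeric(length(time))
  command[in_rise] <- amplitude * t_in[in_rise] / frame_time
  fly <- !in_rise & time < t_end
  if (flyback_time > 0)
    command[fly] <- amplitude *
      pmax(0, 1 - (t_in[fly] - frame_time) / flyback_time)
  # parked at the start position after the last frame
  laser_gate <- in_rise
  trigger_times <- (seq_len(n_frames) - 1L) * period

  structure(
    list(time = time, command = command, laser_gate = laser_gate,
         trigger_times = trigger_times, mode = mode,
         frame_time = frame_time, flyback_time = flyback_time,
         period = period, amplitude = amplitude,
         n_frames = n_frames, sample_rate = sample_rate),
    class = "drive_waveform"
  )
}

#' @export
print.drive_waveform <- function(x, ...) {
  cat(sprintf("Sawtooth drive (%s mode): T = %g ms, flyback = %g ms, period = %g ms\n",
              x$mode, 1e3 * x$frame_time, 1e3 * x$flyback_time, 1e3 * x$period))
  cat(sprintf("  amplitude %.4g um, %d frames, %g Hz sampling\n",
              x$amplitude, x$n_frames, x$sample_rate))
  invisible(x)
}

#' @export
plot.drive_waveform <- function(x, ...) {
  graphics::plot(x$time * 1e3, x$command, type = "l",
                 xlab = "time (ms)", ylab = "commanded position (um)", ...)
  graphics::abline(v = x$trigger_times * 1e3, col = "grey60", lty = 3)
  invisible(x)
}

#' Export a drive waveform as CSV
#'
#' Columns: time (s), command (µm), trigger (0/1 at trigger samples), laser
#' gate (0/1).
#'
#' @param wave A [drive_waveform()].
#' @param path Output CSV path.
#' @export
write_waveform_csv <- function(wave, path) {
  stopifnot(inherits(wave, "drive_waveform"))
  trig <- integer(length(wave$time))
  trig[findInterval(wave$trigger_times, wave$time)] <- 1L
  utils::write.csv(
    data.frame(time_s = wave$time, command_um = wave$command,
               trigger = trig, laser_gate = as.integer(wave$laser_gate)),
    path, row.names = FALSE)
  invisible(path)
}

#' Linear focus actuator model
#'
#' A voice-coil focus actuator modelled as a second-order low-pass system
#' (natural frequency and damping), optionally preceded by a pure transport
#' lag. The default natural frequency is derived from the actuator's quoted
#' response time (3 ms for the supported actuator at full travel) as
#' `omega_n = 6 / response_time` for a critically damped system, i.e. the
#' step response settles within roughly the quoted response time.
#'
#' `response_time = 0` (or `natural_frequency = Inf`) gives an idealized
#' actuator that tracks the command exactly (apart from any `lag`).
#'
#' @param travel_range Travel range, micrometres (spec: 10 mm).
#' @param repeatability Repeatability, micrometres (spec: 50 nm).
#' @param response_time Response time, seconds (spec: 3 ms).
#' @param natural_frequency Second-order natural frequency, rad/s, or `NULL`
#'   to derive from `response_time`.
#' @param damping Damping ratio (> 0).
#' @param lag Pure transport delay, seconds.
#' @return An object of class `lfa_model`.
#' @export
lfa_model <- function(travel_range = 10000, repeatability = 0.05,
                      response_time = 0.003, natural_frequency = NULL,
                      damping = 1, lag = 0) {
  chk_num(travel_range, "travel_range", lower = 0, strict_lower = TRUE)
  chk_num(repeatability, "repeatability", lower = 0)
  chk_num(response_time, "response_time", lower = 0)
  chk_num(lag, "lag", lower = 0)
  if (is.null(natural_frequency)) {
    natural_frequency <- if (response_time > 0) 6 / response_time else Inf
  }
  if (!is.numeric(natural_frequency) || length(natural_frequency) != 1L ||
      is.na(natural_frequency) || natural_frequency <= 0)
    stop("`natural_frequency` must be a positive number (Inf = ideal)",
         call. = FALSE)
  chk_num(damping, "damping", lower = 0, strict_lower = TRUE)
  structure(
    list(travel_range = travel_range, repeatability = repeatability,
         response_time = response_time, natural_frequency = natural_frequency,
         damping = damping, lag = lag),
    class = "lfa_model"
  )
}

#' @export
print.lfa_model <- function(x, ...) {
  cat(sprintf("Focus actuator: travel %g mm, repeatability %g nm, response %g ms\n",
              x$travel_range / 1e3, x$repeatability * 1e3,
              x$response_time * 1e3))
  if (is.finite(x$natural_frequency))
    cat(sprintf("  2nd-order: omega_n = %.4g rad/s, damping = %.3g, lag = %g ms\n",
                x$natural_frequency, x$damping, x$lag * 1e3))
  else
    cat(sprintf("  idealized (no dynamics), lag = %g ms\n", x$lag * 1e3))
  invisible(x)
}

# Shift a sampled signal by a pure delay via linear interpolation.
apply_lag <- function(time, u, lag) {
  if (lag == 0) return(u)
  stats::approx(time, u, xout = time - lag, rule = 2)$y
}

#' Actuator tracking of a drive waveform
#'
#' Integrates the second-order actuator response to the commanded waveform
#' (fourth-order Runge-Kutta on the sampled command with linear interpolation
#' within each step) and returns the tracking error trace. The model is
#' linear and time-invariant, so halving the amplitude halves the error, and
#' slowing the sweep (larger T at fixed amplitude) reduces the rise-phase
#' error.
#'
#' @param wave A [drive_waveform()].
#' @param lfa An [lfa_model()].
#' @return A list of class `lfa_track`: `time`, `command` (the possibly
#'   lag-shifted target actually presented to the dynamics is internal),
#'   `position` (actual trace, µm), `error` (= position - command, µm), and
#'   `max_rise_error` (max |error| over laser-on samples).
#' @export
lfa_track <- function(wave, lfa) {
  stopifnot(inherits(wave, "drive_waveform"), inherits(lfa, "lfa_model"))
  time <- wave$time
  u <- apply_lag(time, wave$command, lfa$lag)
  if (!is.finite(lfa$natural_frequency)) {
    pos <- u
  } else {
    wn <- lfa$natural_frequency
    z <- lfa$damping
    h <- 1 / wave$sample_rate
    if (wn * h > 0.5)
      warning("sample rate is marginal for the actuator dynamics; ",
              "increase `sample_rate`", call. = FALSE)
    nT <- length(time)
    pos <- numeric(nT)
    x <- u[1]
    v <- 0
    deriv <- function(x, v, uu) c(v, wn^2 * (uu - x) - 2 * z * wn * v)
    for (i in seq_len(nT - 1L)) {
      u0 <- u[i]; u1 <- u[i + 1L]; um <- (u0 + u1) / 2
      k1 <- deriv(x, v, u0)
      k2 <- deriv(x + h / 2 * k1[1], v + h / 2 * k1[2], um)
      k3 <- deriv(x + h / 2 * k2[1], v + h / 2 * k2[2], um)
      k4 <- deriv(x + h * k3[1], v + h * k3[2], u1)
      x <- x + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
      v <- v + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
      pos[i + 1L] <- x
    }
    pos[1] <- u[1]
  }
  err <- pos - wave$command
  structure(
    list(time = time, command = wave$command, position = pos, error = err,
         max_rise_error = if (any(wave$laser_gate))
           max(abs(err[wave$laser_gate])) else 0),
    class = "lfa_track"
  )
}

#' Per-row synchronization error map
#'
#' For every camera row, the offset (µm, along the sweep axis) between the
#' actual light-sheet waist position and the row's nominal object plane at
#' the midpoint of the row's exposure window. The nominal plane of a row is
#' where the commanded waveform puts the waist at that instant, so an ideal
#' actuator gives zero offset everywhere; a pure transport lag gives an
#' offset of (sweep slope) x (lag) on interior rows. In dual mode the two
#' shutters share exposure windows and both arms ride the same actuator, so
#' rows `r` and `r + n_rows/2` have identical offsets by construction.
#'
#' @param wave A [drive_waveform()].
#' @param lfa An [lfa_model()].
#' @param cam A [camera_config()]; its mode must match the waveform's.
#' @param frame Which frame (period) to evaluate, default 1.
#' @return Numeric vector of per-row offsets, micrometres, length
#'   `cam$n_rows`.
#' @export
synchronization_map <- function(wave, lfa, cam, frame = 1L) {
  stopifnot(inherits(wave, "drive_waveform"), inherits(cam, "camera_config"))
  if (wave$mode != cam$mode)
    stop(sprintf("waveform mode (%s) and camera mode (%s) disagree",
                 wave$mode, cam$mode), call. = FALSE)
  frame <- chk_count(frame, "frame")
  if (frame > wave$n_frames)
    stop("`frame` exceeds the number of frames in the waveform", call. = FALSE)
  sched <- shutter_schedule(cam, wave$frame_time)
  t_mid <- wave$trigger_times[frame] + row_exposure_midpoints(sched)
  track <- lfa_track(wave, lfa)
  actual <- stats::approx(track$time, track$position, xout = t_mid, rule = 2)$y
  commanded <- stats::approx(track$time, track$command, xout = t_mid, rule = 2)$y
  actual - commanded
}
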
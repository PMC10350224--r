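#' sCMOS camera configuration
#'
#' Rolling-shutter geometry and noise model of the detection camera. In
#' `single` mode one band of `shutter_width` active rows sweeps the full
#' frame during one frame time. In `dual` mode two synchronized bands sweep
#' concurrently, each covering half the frame; their row indices differ by
#' `n_rows / 2` at all times. Readout is unidirectional (the supported camera
#' cannot reverse its readout between frames, which is why a flyback phase
#' exists at all).
#'
#' @param n_rows,n_cols Sensor geometry in pixels; `n_rows` must be even in
#'   dual mode.
#' @param shutter_width Active band width W in rows. Single mode allows
#'   `1 <= W <= n_rows`; dual mode `1 <= W <= n_rows / 2`.
#' @param mode `"single"` (traditional axially swept acquisition) or
#'   `"dual"` (dual-foci, two rolling shutters).
#' @param offset_counts Dark offset added to every pixel, counts.
#' @param read_noise_counts Gaussian read noise standard deviation, counts.
#' @param conversion_gain Counts per photoelectron.
#' @param bit_depth Output bit depth; counts are clipped to `2^bit_depth - 1`.
#' @return An object of class `camera_config`.
#' @examples
#' camera_config(mode = "dual", shutter_width = 256)
#' @export
camera_config <- function(n_rows = 2048L, n_cols = 2048L,
                          shutter_width = 256L,
                          mode = c("single", "dual"),
                          offset_counts = 100,
                          read_noise_counts = 2,
                          conversion_gain = 0.46,
                          bit_depth = 16L) {
  mode <- match.arg(mode)
  n_rows <- chk_count(n_rows, "n_rows")
  n_cols <- chk_count(n_cols, "n_cols")
  shutter_width <- chk_count(shutter_width, "shutter_width")
  chk_num(offset_counts, "offset_counts", lower = 0)
  chk_num(read_noise_counts, "read_noise_counts", lower = 0)
  chk_num(conversion_gain, "conversion_gain", lower = 0, strict_lower = TRUE)
  bit_depth <- chk_count(bit_depth, "bit_depth")
  if (mode == "dual" && n_rows %% 2L != 0L)
    stop("dual mode requires an even number of rows", call. = FALSE)
  w_max <- if (mode == "dual") n_rows %/% 2L else n_rows
  if (shutter_width < 1L || shutter_width > w_max)
    stop(sprintf("shutter_width must be in [1, %d] for %s mode", w_max, mode),
         call. = FALSE)
  structure(
    list(n_rows = n_rows, n_cols = n_cols, shutter_width = shutter_width,
         mode = mode, offset_counts = offset_counts,
         read_noise_counts = read_noise_counts,
         conversion_gain = conversion_gain, bit_depth = bit_depth),
    class = "camera_config"
  )
}

#' @export
print.camera_config <- function(x, ...) {
  cat(sprintf("sCMOS camera: %d x %d px, %s-shutter mode, W = %d rows\n",
              x$n_rows, x$n_cols, x$mode, x$shutter_width))
  cat(sprintf("  offset %.3g counts, read noise %.3g counts, gain %.3g ct/e-\n",
              x$offset_counts, x$read_noise_counts, x$conversion_gain))
  invisible(x)
}

#' Rolling-shutter exposure schedule
#'
#' Computes the per-row activation window for one frame of duration `T`
#' (seconds). In single mode the band steps through all `n_rows` rows, so row
#' `r` (0-based) is active on `[r * tau, r * tau + W * tau)` with
#' `tau = T / n_rows`. In dual mode the two bands step through `n_rows / 2`
#' rows each in the same frame time, so the row period is
#' `tau_d = T / (n_rows / 2)` and rows `r` and `r + n_rows/2` share the same
#' window. The per-row exposure is therefore `W * T / n_rows` (single) versus
#' `W * T / (n_rows / 2)` (dual): at equal frame time and shutter width the
#' active pixels in dual mode are exposed exactly twice as long, which is the
#' source of the two-fold signal gain of dual-foci acquisition.
#'
#' @param cam A [camera_config()] object.
#' @param frame_time Frame (sweep) time T in seconds.
#' @return An object of class `shutter_schedule`: a list with `t_on`, `t_off`
#'   (numeric vectors of length `n_rows`, seconds, row `r`'s window is
#'   `[t_on[r+1], t_off[r+1])`), `row_exposure` (seconds, identical for all
#'   rows), `row_period`, `mode` and `frame_time`.
#' @examples
#' s <- shutter_schedule(camera_config(mode = "single", shutter_width = 1),
#'                       frame_time = 0.1)
#' s$row_exposure  # 0.1 / 2048
#' @export
shutter_schedule <- function(cam, frame_time) {
  stopifnot(inherits(cam, "camera_config"))
  chk_num(frame_time, "frame_time", lower = 0, strict_lower = TRUE)
  n <- cam$n_rows
  W <- cam$shutter_width
  if (cam$mode == "single") {
    tau <- frame_time / n
    r <- 0:(n - 1L)
    t_on <- r * tau
  } else {
    half <- n %/% 2L
    tau <- frame_time / half
    r <- c(0:(half - 1L), 0:(half - 1L))  # rows r and r + half share windows
    t_on <- r * tau
  }
  structure(
    list(t_on = t_on, t_off = t_on + W * tau,
         row_exposure = W * tau, row_period = tau,
         mode = cam$mode, frame_time = frame_time, n_rows = n,
         shutter_width = W),
    class = "shutter_schedule"
  )
}

#' @export
print.shutter_schedule <- function(x, ...) {
  cat(sprintf("%s-shutter schedule: T = %g s, W = %d rows\n",
              x$mode, x$frame_time, x$shutter_width))
  cat(sprintf("  per-row exposure %.6g s, row period %.6g s\n",
              x$row_exposure, x$row_period))
  invisible(x)
}

#' Exposure midpoint of each row
#'
#' @param schedule A [shutter_schedule()].
#' @return Numeric vector of length `n_rows`, seconds.
#' @export
row_exposure_midpoints <- function(schedule) {
  stopifnot(inherits(schedule, "shutter_schedule"))
  (schedule$t_on + schedule$t_off) / 2
}
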
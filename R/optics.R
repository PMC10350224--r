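#' Gaussian light-sheet beam parameters
#'
#' Describes the illumination light sheet as a Gaussian beam. The sheet
#' thickness follows the usual divergence law around the waist, and the
#' Rayleigh range is kept consistent with the waist radius, wavelength and
#' immersion refractive index: \eqn{z_R = \pi w_0^2 n / \lambda}.
#'
#' @param wavelength Emission/illumination wavelength in micrometres.
#' @param refractive_index Immersion refractive index (>= 1).
#' @param waist_radius Beam waist radius \eqn{w_0} in micrometres.
#' @return An object of class `beam_parameters` with fields `wavelength`,
#'   `refractive_index`, `waist_radius` and the derived `rayleigh_range` (µm).
#' @examples
#' b <- beam_parameters(wavelength = 0.488, refractive_index = 1.33,
#'                      waist_radius = 0.5)
#' b$rayleigh_range
#' @export
beam_parameters <- function(wavelength = 0.488, refractive_index = 1.33,
                            waist_radius = 0.5) {
  chk_num(wavelength, "wavelength", lower = 0, strict_lower = TRUE)
  chk_num(refractive_index, "refractive_index", lower = 1)
  chk_num(waist_radius, "waist_radius", lower = 0, strict_lower = TRUE)
  structure(
    list(
      wavelength = wavelength,
      refractive_index = refractive_index,
      waist_radius = waist_radius,
      rayleigh_range = pi * waist_radius^2 * refractive_index / wavelength
    ),
    class = "beam_parameters"
  )
}

#' @export
print.beam_parameters <- function(x, ...) {
  cat("Gaussian light-sheet beam\n")
  cat(sprintf("  wavelength      : %.4g um\n", x$wavelength))
  cat(sprintf("  immersion index : %.4g\n", x$refractive_index))
  cat(sprintf("  waist radius w0 : %.4g um\n", x$waist_radius))
  cat(sprintf("  Rayleigh range  : %.4g um\n", x$rayleigh_range))
  invisible(x)
}

#' Gaussian beam radius at an axial offset
#'
#' Evaluates \eqn{w(z) = w_0 \sqrt{1 + (z/z_R)^2}} along the propagation axis,
#' i.e. the half-thickness of the light sheet at distance `z` from the waist.
#'
#' @param beam A [beam_parameters()] object.
#' @param z Axial offset(s) from the waist, micrometres. Vectorised.
#' @return Beam radius in micrometres, same length as `z`.
#' @export
beam_radius <- function(beam, z) {
  stopifnot(inherits(beam, "beam_parameters"))
  if (!is.numeric(z) || any(!is.finite(z)))
    stop("`z` must be finite numeric", call. = FALSE)
  beam$waist_radius * sqrt(1 + (z / beam$rayleigh_range)^2)
}

#' Multi-immersion optical scaling
#'
#' Magnification in a multi-immersion detection path scales with the immersion
#' refractive index. The model is anchored at a measured calibration point
#' (15.28x in water, n = 1.33) and assumed linear in n:
#' \eqn{M(n) = M_{ref} \, n / n_{ref}}. Pixel size in sample space is the
#' sensor pitch divided by the magnification, so
#' `pixel_size(n) * magnification(n) == sensor_pitch` for every n.
#'
#' @param reference_magnification Measured magnification at `reference_index`.
#' @param reference_index Refractive index of the calibration point.
#' @param sensor_pitch Physical sensor pixel pitch, micrometres.
#' @param n_rows,n_cols Sensor geometry in pixels.
#' @return An object of class `immersion_scaling`.
#' @examples
#' sc <- immersion_scaling()
#' pixel_size(sc, 1.33)    # 0.425 um in water
#' field_of_view(sc, 1.33) # ~870 um
#' @export
immersion_scaling <- function(reference_magnification = 15.28,
                              reference_index = 1.33,
                              sensor_pitch = 6.5,
                              n_rows = 2048L, n_cols = 2048L) {
  chk_num(reference_magnification, "reference_magnification", lower = 0,
          strict_lower = TRUE)
  chk_num(reference_index, "reference_index", lower = 1)
  chk_num(sensor_pitch, "sensor_pitch", lower = 0, strict_lower = TRUE)
  structure(
    list(
      reference_magnification = reference_magnification,
      reference_index = reference_index,
      sensor_pitch = sensor_pitch,
      n_rows = chk_count(n_rows, "n_rows"),
      n_cols = chk_count(n_cols, "n_cols")
    ),
    class = "immersion_scaling"
  )
}

#' @export
print.immersion_scaling <- function(x, ...) {
  cat("Multi-immersion scaling\n")
  cat(sprintf("  reference: %.4gx at n = %.4g\n",
              x$reference_magnification, x$reference_index))
  cat(sprintf("  sensor: %d x %d px, pitch %.3g um\n",
              x$n_rows, x$n_cols, x$sensor_pitch))
  cat(sprintf("  in water (n=1.33): pixel %.4g um, FOV %.4g um\n",
              pixel_size(x, 1.33), field_of_view(x, 1.33)))
  invisible(x)
}

#' Magnification at an immersion refractive index
#' @param scaling An [immersion_scaling()] object.
#' @param n Immersion refractive index (>= 1). Vectorised.
#' @return Magnification (dimensionless).
#' @export
magnification <- function(scaling, n) {
  stopifnot(inherits(scaling, "immersion_scaling"))
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 1))
    stop("refractive index `n` must be finite and >= 1", call. = FALSE)
  scaling$reference_magnification * n / scaling$reference_index
}

#' Sample-space pixel size at an immersion refractive index
#' @inheritParams magnification
#' @return Pixel size in micrometres.
#' @export
pixel_size <- function(scaling, n) {
  scaling$sensor_pitch / magnification(scaling, n)
}

#' Field of view along the row axis at an immersion refractive index
#' @inheritParams magnification
#' @return Field of view in micrometres (`n_rows * pixel_size`).
#' @export
field_of_view <- function(scaling, n) {
  scaling$n_rows * pixel_size(scaling, n)
}

#' Dual-arm remote-focusing geometry
#'
#' Two remote-focusing arms carry mirrors displaced by equal and opposite
#' offsets (+dz, -dz) about the nominal focus, producing two light-sheet foci
#' at a fixed separation in the image. Mirror displacement maps to sample-space
#' focus displacement through the axial gain `g` (sample-µm per mirror-µm).
#'
#' Neither the mirror offset nor the gain is measured independently here;
#' only their product matters for the separation. When `axial_gain` is left
#' `NULL` it is calibrated jointly with `mirror_offset` so that the separation
#' equals `calibration_rows` (default 1024, half the frame) at the calibration
#' scaling and index — the instrument's documented operating point.
#'
#' @param mirror_offset Per-arm mirror offset dz, micrometres (signed).
#' @param axial_gain Axial gain g (> 0), sample-µm per mirror-µm, or `NULL`
#'   to calibrate from `calibration_rows`.
#' @param calibration_rows Target separation, camera rows, used only when
#'   `axial_gain` is `NULL`.
#' @param calibration_scaling,calibration_index Scaling model and immersion
#'   index at which the calibration holds.
#' @return An object of class `remote_focus_geometry`.
#' @export
remote_focus_geometry <- function(mirror_offset = 100, axial_gain = NULL,
                                  calibration_rows = 1024L,
                                  calibration_scaling = immersion_scaling(),
                                  calibration_index = 1.33) {
  chk_num(mirror_offset, "mirror_offset")
  if (is.null(axial_gain)) {
    chk_count(calibration_rows, "calibration_rows")
    if (mirror_offset == 0)
      stop("cannot calibrate axial gain with a zero mirror offset",
           call. = FALSE)
    axial_gain <- calibration_rows *
      pixel_size(calibration_scaling, calibration_index) /
      (2 * abs(mirror_offset))
  }
  chk_num(axial_gain, "axial_gain", lower = 0, strict_lower = TRUE)
  structure(
    list(mirror_offset = mirror_offset, axial_gain = axial_gain),
    class = "remote_focus_geometry"
  )
}

#' Focus separation in camera rows
#'
#' The two foci sit at +/- `g * |dz|` about the nominal focus, so their
#' separation in sample space is `2 g |dz|`; dividing by the pixel size at the
#' working refractive index and rounding to the nearest row (ties away from
#' zero) gives the separation in rows. The default geometry returns 1024 rows
#' (half of a 2048-row frame) in water.
#'
#' @param geom A [remote_focus_geometry()] object.
#' @param scaling An [immersion_scaling()] object.
#' @param n Immersion refractive index.
#' @return Integer number of rows separating the two foci.
#' @examples
#' focus_separation_rows(remote_focus_geometry(), immersion_scaling(), 1.33)
#' @export
focus_separation_rows <- function(geom, scaling, n) {
  stopifnot(inherits(geom, "remote_focus_geometry"))
  if (!is.finite(geom$axial_gain) || geom$axial_gain <= 0)
    stop("axial gain is uncalibrated", call. = FALSE)
  sep_um <- 2 * geom$axial_gain * abs(geom$mirror_offset)
  as.integer(round_half_away(sep_um / pixel_size(scaling, n)))
}
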
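#' Maximum intensity projection
#'
#' @param stack A 3D numeric array or a `sim_stack`.
#' @param axis Axis to project along (1 = rows, 2 = cols, 3 = planes).
#' @return A 2D matrix of per-pixel maxima.
#' @export
mip <- function(stack, axis = 3L) {
  x <- if (inherits(stack, "sim_stack")) stack$counts else stack
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("`stack` must be a 3D array", call. = FALSE)
  if (any(dim(x) == 0L)) stop("`stack` is empty", call. = FALSE)
  axis <- chk_count(axis, "axis")
  if (!axis %in% 1:3) stop("`axis` must be 1, 2 or 3", call. = FALSE)
  if (axis == 3L) {
    out <- x[, , 1L]
    for (k in seq_len(dim(x)[3])[-1L]) out <- pmax(out, x[, , k])
    out
  } else {
    apply(x, setdiff(1:3, axis), max)
  }
}

#' Detect bead candidates in a stack
#'
#' Local maxima (26-neighbourhood) above an intensity threshold, followed by
#' greedy non-maximum suppression so that surviving peaks are at least
#' `min_separation` voxels apart.
#'
#' @param stack A 3D array or `sim_stack`.
#' @param threshold Absolute intensity threshold.
#' @param min_separation Minimum peak separation, voxels (Euclidean).
#' @return A data frame with columns `row`, `col`, `plane`, `value`, ordered
#'   by decreasing intensity; zero rows when nothing is found.
#' @export
detect_beads <- function(stack, threshold, min_separation = 5) {
  x <- if (inherits(stack, "sim_stack")) stack$counts else stack
  stopifnot(is.array(x), length(dim(x)) == 3L)
  chk_num(threshold, "threshold", lower = 0, strict_lower = TRUE)
  chk_num(min_separation, "min_separation", lower = 0)
  d <- dim(x)
  cand <- which(x > threshold, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(row = integer(), col = integer(), plane = integer(),
                      value = numeric()))
  is_max <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]; p <- cand[i, 3]
    nb <- x[max(1, r - 1):min(d[1], r + 1),
            max(1, c - 1):min(d[2], c + 1),
            max(1, p - 1):min(d[3], p + 1)]
    is_max[i] <- x[r, c, p] >= max(nb)
  }
  cand <- cand[is_max, , drop = FALSE]
  vals <- x[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    d2 <- rowSums((prev - matrix(cand[i, ], nrow(prev), 3, byrow = TRUE))^2)
    keep[i] <- all(d2 >= min_separation^2)
  }
  out <- data.frame(row = cand[keep, 1], col = cand[keep, 2],
                    plane = cand[keep, 3], value = vals[keep])
  rownames(out) <- NULL
  out
}

# 1D Gaussian fit with background floor: y ~ floor + A exp(-(t-mu)^2/(2 s^2)).
fit_gauss_1d <- function(y) {
  t <- seq_along(y)
  floor0 <- min(y)
  a0 <- max(y) - floor0
  mu0 <- t[which.max(y)]
  sig0 <- max(1, sum(y - floor0 > a0 / 2) / FWHM_FACTOR)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ fl + A * exp(-(t - mu)^2 / (2 * sig^2)),
      start = list(fl = floor0, A = a0, mu = mu0, sig = sig0),
      lower = c(-Inf, 0, min(t), 1e-3),
      upper = c(Inf, Inf, max(t), length(t)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(sigma = unname(cf[["sig"]]), mu = unname(cf[["mu"]]),
       amplitude = unname(cf[["A"]]), floor = unname(cf[["fl"]]),
       r_squared = if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 0)
}

#' Bead FWHM measurement
#'
#' Fits 1D Gaussians (with a background-floor parameter) to the intensity
#' profiles through the bead centroid along each axis and converts the fitted
#' sigmas to FWHM in micrometres: `FWHM = 2 sqrt(2 ln 2) * sigma * voxel`.
#'
#' @param stack A 3D array or `sim_stack`.
#' @param centroid Integer voxel coordinates `(row, col, plane)` of the bead,
#'   e.g. one row of [detect_beads()].
#' @param voxel_size Voxel size, µm: scalar or length-3 `(row, col, plane)`.
#'   Defaults to the stack's own voxel size for a `sim_stack`.
#' @param window Half-width of the profile window, voxels.
#' @return An object of class `bead_measurement`: `centroid_vox`,
#'   `centroid_um`, `fwhm` (named c(y, x, z), µm: y along rows, x along
#'   columns, z along planes), `fit_quality` (min per-axis R^2, in [0,1]),
#'   and `ok` (FALSE when any axis fit failed; such measurements should be
#'   excluded from summaries).
#' @export
bead_fwhm <- function(stack, centroid, voxel_size = NULL, window = 12L) {
  x <- if (inherits(stack, "sim_stack")) stack$counts else stack
  stopifnot(is.array(x), length(dim(x)) == 3L)
  if (is.null(voxel_size)) {
    if (inherits(stack, "sim_stack")) voxel_size <- stack$voxel_size
    else stop("`voxel_size` required for a plain array", call. = FALSE)
  }
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  centroid <- as.integer(round(as.numeric(centroid)[1:3]))
  d <- dim(x)
  if (any(centroid < 1L) || any(centroid > d))
    stop("centroid outside the stack", call. = FALSE)

  prof <- function(axis) {
    idx <- lapply(1:3, function(a) {
      if (a == axis)
        max(1L, centroid[a] - window):min(d[a], centroid[a] + window)
      else centroid[a]
    })
    as.numeric(x[idx[[1]], idx[[2]], idx[[3]]])
  }
  fits <- lapply(1:3, function(a) fit_gauss_1d(prof(a)))
  ok <- !vapply(fits, is.null, TRUE)
  fwhm <- rep(NA_real_, 3)
  qual <- rep(NA_real_, 3)
  for (a in 1:3) {
    if (ok[a]) {
      fwhm[a] <- sigma_to_fwhm(fits[[a]]$sigma) * voxel_size[a]
      qual[a] <- fits[[a]]$r_squared
    }
  }
  structure(
    list(centroid_vox = centroid,
         centroid_um = (centroid - 0.5) * voxel_size,
         fwhm = c(y = fwhm[1], x = fwhm[2], z = fwhm[3]),
         fit_quality = if (all(ok)) min(qual) else 0,
         ok = all(ok)),
    class = "bead_measurement"
  )
}

#' @export
print.bead_measurement <- function(x, ...) {
  cat(sprintf("Bead at voxel (%d, %d, %d): FWHM y/x/z = %.3g / %.3g / %.3g um (R2 = %.3f)%s\n",
              x$centroid_vox[1], x$centroid_vox[2], x$centroid_vox[3],
              x$fwhm[["y"]], x$fwhm[["x"]], x$fwhm[["z"]], x$fit_quality,
              if (x$ok) "" else " [fit failed]"))
  invisible(x)
}

#' Measure all beads in a stack
#'
#' Convenience wrapper: detect beads, fit each, and return a measurement
#' table of the kind used for resolution summaries (mean +/- sd, n). Failed
#' fits are flagged and excluded.
#'
#' @inheritParams detect_beads
#' @inheritParams bead_fwhm
#' @param file Optional CSV path for the measurement table.
#' @return A data frame: bead id, centroid (voxels), `fwhm_y`, `fwhm_x`,
#'   `fwhm_z` (µm), `fit_quality`, `ok`.
#' @export
measure_beads <- function(stack, threshold, min_separation = 5,
                          voxel_size = NULL, window = 12L, file = NULL) {
  det <- detect_beads(stack, threshold, min_separation)
  rows <- lapply(seq_len(nrow(det)), function(i) {
    m <- bead_fwhm(stack, c(det$row[i], det$col[i], det$plane[i]),
                   voxel_size = voxel_size, window = window)
    data.frame(id = i, row = det$row[i], col = det$col[i],
               plane = det$plane[i],
               fwhm_y = m$fwhm[["y"]], fwhm_x = m$fwhm[["x"]],
               fwhm_z = m$fwhm[["z"]],
               fit_quality = m$fit_quality, ok = m$ok)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), row = integer(), col = integer(),
               plane = integer(), fwhm_y = numeric(), fwhm_x = numeric(),
               fwhm_z = numeric(), fit_quality = numeric(), ok = logical())
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Convert a measured width between immersion refractive indices
#'
#' In a multi-immersion system a fixed camera-space extent corresponds to a
#' sample-space length proportional to 1/n, so a width measured at `n_from`
#' corresponds to `value * n_from / n_to` at `n_to` (e.g. 0.97 µm in water,
#' n = 1.33, is equivalent to 0.83 µm at n = 1.56).
#'
#' @param value Width(s), µm.
#' @param n_from,n_to Refractive indices (>= 1).
#' @return Converted width(s), µm.
#' @examples
#' convert_fwhm(0.97, 1.33, 1.56)
#' @export
convert_fwhm <- function(value, n_from, n_to) {
  chk_num(n_from, "n_from", lower = 1)
  chk_num(n_to, "n_to", lower = 1)
  value * n_from / n_to
}

# Embed a (smaller) PSF centred in an array of dim `d`.
embed_psf <- function(psf, d) {
  pd <- dim(psf)
  if (any(pd > d)) stop("psf larger than the padded stack", call. = FALSE)
  out <- array(0, dim = d)
  start <- (d %/% 2) - (pd %/% 2) + 1L
  out[start[1]:(start[1] + pd[1] - 1L),
      start[2]:(start[2] + pd[2] - 1L),
      start[3]:(start[3] + pd[3] - 1L)] <- psf
  out
}

mirror_pad <- function(x, pad) {
  d <- dim(x)
  idx <- lapply(1:3, function(a) {
    n <- d[a]; p <- min(pad[a], n)
    c(if (p > 0) p:1, 1:n, if (p > 0) n:(n - p + 1L))
  })
  list(x = x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
       pad = pmin(pad, d))
}

#' Richardson-Lucy deconvolution
#'
#' Iterative maximum-likelihood deconvolution for Poisson data. Boundary
#' handling is by reflective padding (half the PSF support on each face), so
#' the total intensity of interior objects is conserved to within about 1%.
#'
#' @param stack A 3D array or `sim_stack` (non-negative).
#' @param psf A 3D array; normalized internally to unit sum (an error if the
#'   sum is non-positive or non-finite).
#' @param n_iter Number of iterations (default 10).
#' @return The deconvolved 3D array (non-negative), same dimensions as the
#'   input.
#' @export
richardson_lucy <- function(stack, psf, n_iter = 10L) {
  x <- if (inherits(stack, "sim_stack")) stack$counts else stack
  stopifnot(is.array(x), length(dim(x)) == 3L)
  if (!is.array(psf) || length(dim(psf)) != 3L)
    stop("`psf` must be a 3D array", call. = FALSE)
  n_iter <- chk_count(n_iter, "n_iter")
  s <- sum(psf)
  if (!is.finite(s) || s <= 0)
    stop("psf is not normalizable (sum <= 0 or non-finite)", call. = FALSE)
  psf <- psf / s
  x <- pmax(x, 0)
  storage.mode(x) <- "double"

  pad <- pmin(dim(psf) %/% 2L + 1L, dim(x))
  mp <- mirror_pad(x, pad)
  xp <- mp$x
  pad <- mp$pad
  d <- dim(xp)
  K <- embed_psf(psf, d)
  Kf <- stats::fft(local({
    ctr <- (d %/% 2) + 1L
    k <- K
    for (a in 1:3) {
      idx <- c(ctr[a]:d[a], seq_len(ctr[a] - 1L))
      k <- switch(a, k[idx, , , drop = FALSE], k[, idx, , drop = FALSE],
                  k[, , idx, drop = FALSE])
    }
    k
  }))
  Kf_flip <- Conj(Kf)  # correlation = convolution with the flipped kernel
  conv_with <- function(a, Kfreq)
    pmax(Re(stats::fft(stats::fft(a) * Kfreq, inverse = TRUE)) / prod(d), 0)

  est <- xp
  eps <- 1e-12
  for (it in seq_len(n_iter)) {
    denom <- conv_with(est, Kf)
    ratio <- xp / pmax(denom, eps)
    est <- est * conv_with(ratio, Kf_flip)
  }
  est[(pad[1] + 1L):(pad[1] + dim(x)[1]),
      (pad[2] + 1L):(pad[2] + dim(x)[2]),
      (pad[3] + 1L):(pad[3] + dim(x)[3])]
}

#' Signal-to-noise ratio of a stack region
#'
#' `snr = (mean(foreground) - mean(background)) / sd(background)`. The
#' foreground and background are given as disjoint logical masks over the
#' stack.
#'
#' @param stack A 3D array (or 2D matrix, or `sim_stack`).
#' @param fg_mask,bg_mask Logical arrays of the same dimensions, disjoint
#'   and non-empty.
#' @return An object of class `snr_result` with `mean_signal`,
#'   `mean_background`, `sd_background`, `snr`.
#' @export
snr <- function(stack, fg_mask, bg_mask) {
  x <- if (inherits(stack, "sim_stack")) stack$counts else stack
  if (!identical(dim(x), dim(fg_mask)) || !identical(dim(x), dim(bg_mask)))
    stop("masks must match the stack dimensions", call. = FALSE)
  if (!any(fg_mask) || !any(bg_mask))
    stop("both masks must be non-empty", call. = FALSE)
  if (any(fg_mask & bg_mask))
    stop("foreground and background masks must be disjoint", call. = FALSE)
  mfg <- mean(x[fg_mask])
  mbg <- mean(x[bg_mask])
  sbg <- stats::sd(x[bg_mask])
  if (!is.finite(sbg) || sbg == 0)
    stop("background standard deviation is zero; SNR undefined",
         call. = FALSE)
  structure(
    list(mean_signal = mfg, mean_background = mbg, sd_background = sbg,
         snr = (mfg - mbg) / sbg),
    class = "snr_result"
  )
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf("SNR = %.3f (signal %.4g, background %.4g +/- %.4g)\n",
              x$snr, x$mean_signal, x$mean_background, x$sd_background))
  invisible(x)
}
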
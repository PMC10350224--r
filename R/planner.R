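# 1D covering of an extent by tiles of size `tile` with fractional overlap.
# Minimal number of tiles; the last tile is placed flush with the far edge.
cover_axis <- function(extent, tile, overlap) {
  if (extent <= tile) return(0)
  stride <- (1 - overlap) * tile
  k <- ceiling((extent - tile) / stride) + 1
  starts <- (seq_len(k) - 1) * stride
  starts[k] <- extent - tile
  starts
}

#' Plan a tiled acquisition over a bounding box
#'
#' Lays out overlapping tiles covering a rectangular sample volume. Lateral
#' tile size is the field of view at the working immersion index; tiles
#' overlap by the given fraction in all three dimensions, with per-axis tile
#' counts chosen minimally and the final tile flush with the box edge. The
#' stage steps axially by one lateral pixel per frame (matching the pixel
#' size for the immersion medium), so a stack of depth `tile_depth` has
#' `ceiling(tile_depth / pixel_size)` frames.
#'
#' @param box Bounding box extents `(x, y, z)`, µm.
#' @param n Immersion refractive index.
#' @param overlap Overlap fraction between neighbouring tiles, in [0, 0.9].
#' @param tile_depth Axial depth of one tile stack, µm.
#' @param channels Number of colour channels acquired per position.
#' @param scaling An [immersion_scaling()].
#' @return An object of class `tile_plan`: `positions` (data frame of tile
#'   start corners x/y/z, µm, in acquisition order), `n_stacks` (positions
#'   per channel), `frames_per_stack`, `channels`, and the geometry
#'   parameters.
#' @examples
#' plan_tiles(c(4200, 3300, 5500), n = 1.52, tile_depth = 140)
#' @export
plan_tiles <- function(box, n = 1.33, overlap = 0.1, tile_depth = 140,
                       channels = 1L, scaling = immersion_scaling()) {
  if (!is.numeric(box) || length(box) != 3L || any(box <= 0))
    stop("`box` must be three positive extents (x, y, z) in um",
         call. = FALSE)
  chk_num(overlap, "overlap", lower = 0, upper = 0.9)
  channels <- chk_count(channels, "channels")
  px <- pixel_size(scaling, n)
  if (tile_depth < px)
    stop(sprintf("tile_depth (%g um) is smaller than one axial step (%g um)",
                 tile_depth, px), call. = FALSE)
  fov_x <- scaling$n_cols * px
  fov_y <- scaling$n_rows * px
  xs <- cover_axis(box[1], fov_x, overlap)
  ys <- cover_axis(box[2], fov_y, overlap)
  zs <- cover_axis(box[3], tile_depth, overlap)
  grid <- expand.grid(x = xs, y = ys, z = zs,
                      KEEP.OUT.ATTRS = FALSE)
  structure(
    list(positions = grid,
         n_stacks = nrow(grid),
         frames_per_stack = as.integer(ceiling(tile_depth / px)),
         channels = channels,
         box = box, n = n, overlap = overlap,
         tile_depth = tile_depth, pixel_size = px,
         tile_size = c(x = fov_x, y = fov_y, z = tile_depth),
         scaling = scaling),
    class = "tile_plan"
  )
}

#' @export
print.tile_plan <- function(x, ...) {
  cat(sprintf("Tile plan: %d stacks x %d channels, %d frames per stack\n",
              x$n_stacks, x$channels, x$frames_per_stack))
  cat(sprintf("  box %g x %g x %g um at n = %g, overlap %.0f%%\n",
              x$box[1], x$box[2], x$box[3], x$n, 100 * x$overlap))
  cat(sprintf("  tile %g x %g x %g um, axial step %.4g um\n",
              x$tile_size[1], x$tile_size[2], x$tile_size[3],
              x$pixel_size))
  invisible(x)
}

#' Total per-frame acquisition time for a tiled acquisition
#'
#' The cumulative pfAT is `n_stacks * frames_per_stack * frame_time`: the
#' pure sweep time summed over every frame of every stack, excluding flyback
#' and stack delays.
#'
#' @param n_stacks Number of stacks (tiles x channels as appropriate).
#' @param frames_per_stack Frames per stack.
#' @param frame_time Per-frame sweep time, seconds.
#' @return A list of class `pfat_total`: `seconds`, and `hours` rounded to 2
#'   decimal places (round-half-even).
#' @examples
#' pfat_total(1672, 425, 0.025)$hours  # 4.93
#' @export
pfat_total <- function(n_stacks, frames_per_stack, frame_time) {
  chk_num(n_stacks, "n_stacks", lower = 0)
  chk_num(frames_per_stack, "frames_per_stack", lower = 0)
  chk_num(frame_time, "frame_time", lower = 0)
  secs <- n_stacks * frames_per_stack * frame_time
  structure(list(seconds = secs, hours = round(secs / 3600, 2)),
            class = "pfat_total")
}

#' @export
print.pfat_total <- function(x, ...) {
  cat(sprintf("total pfAT: %.6g s (%.2f h)\n", x$seconds, x$hours))
  invisible(x)
}

#' Total imaging time budget
#'
#' Adds the two overheads to the cumulative pfAT: flyback after every frame,
#' and a stack delay between consecutive stacks (stage motion, filter wheel,
#' data writing). `total = pfat + n_frames * flyback +
#' (n_stacks * channels - 1) * stack_delay`. Also reports the dataset size.
#'
#' @param plan A [plan_tiles()] result.
#' @param frame_time Per-frame sweep time, seconds.
#' @param flyback Flyback time per frame, seconds.
#' @param stack_delay Delay between consecutive stacks, seconds.
#' @param bytes_per_voxel Bytes per voxel for the size estimate.
#' @return An object of class `timing_budget` with `pfat_total_s`,
#'   `flyback_total_s`, `stack_delay_total_s`, `total_imaging_time_s`,
#'   corresponding `_h` fields (2 d.p.), and `dataset_bytes`.
#' @export
total_imaging_time <- function(plan, frame_time, flyback = 0,
                               stack_delay = 0, bytes_per_voxel = 2) {
  stopifnot(inherits(plan, "tile_plan"))
  chk_num(frame_time, "frame_time", lower = 0)
  chk_num(flyback, "flyback", lower = 0)
  chk_num(stack_delay, "stack_delay", lower = 0)
  n_stacks_total <- plan$n_stacks * plan$channels
  n_frames_total <- n_stacks_total * plan$frames_per_stack
  pfat <- n_frames_total * frame_time
  fly <- n_frames_total * flyback
  sd_total <- max(0, n_stacks_total - 1) * stack_delay
  total <- pfat + fly + sd_total
  structure(
    list(pfat_total_s = pfat, flyback_total_s = fly,
         stack_delay_total_s = sd_total, total_imaging_time_s = total,
         pfat_total_h = round(pfat / 3600, 2),
         total_imaging_time_h = round(total / 3600, 2),
         n_stacks_total = n_stacks_total, n_frames_total = n_frames_total,
         dataset_bytes = dataset_bytes(plan, bytes_per_voxel)),
    class = "timing_budget"
  )
}

#' @export
print.timing_budget <- function(x, ...) {
  cat(sprintf("Timing budget: %d stacks, %d frames\n",
              x$n_stacks_total, x$n_frames_total))
  cat(sprintf("  pfAT        %.2f h\n", x$pfat_total_s / 3600))
  cat(sprintf("  flyback     %.2f h\n", x$flyback_total_s / 3600))
  cat(sprintf("  stack delay %.2f h\n", x$stack_delay_total_s / 3600))
  cat(sprintf("  total       %.2f h\n", x$total_imaging_time_s / 3600))
  cat(sprintf("  dataset     %.2f TB\n", x$dataset_bytes / 1e12))
  invisible(x)
}

#' Dataset size of a tiled acquisition
#'
#' `n_stacks * channels * n_rows * n_cols * frames_per_stack *
#' bytes_per_voxel`, in bytes (decimal TB = 1e12 bytes when reported).
#'
#' @param plan A [plan_tiles()] result, or a list with fields `n_stacks`,
#'   `channels`, `frames_per_stack` and `scaling`.
#' @param bytes_per_voxel Bytes per voxel (2 for 16-bit).
#' @return Total size in bytes.
#' @export
dataset_bytes <- function(plan, bytes_per_voxel = 2) {
  chk_num(bytes_per_voxel, "bytes_per_voxel", lower = 0, strict_lower = TRUE)
  plan$n_stacks * plan$channels *
    as.numeric(plan$scaling$n_rows) * plan$scaling$n_cols *
    plan$frames_per_stack * bytes_per_voxel
}

#' Compare single- and dual-shutter acquisition configurations
#'
#' Side-by-side comparison of the two acquisition modes: frame time, frame
#' rate, per-row exposure, cumulative pfAT for an optional tile plan, and the
#' predicted SNR-ratio bounds (read-noise-dominated to shot-noise-limited)
#' implied by the per-row exposure ratio.
#'
#' @param single,dual Lists with fields `cam` (a [camera_config()] of the
#'   matching mode) and `frame_time` (seconds). Defaults are the reference
#'   configurations: single at 100 ms, dual at 25 ms, equal shutter width.
#' @param plan Optional [plan_tiles()] result for cumulative pfAT totals.
#' @return An object of class `mode_comparison`: `table` (one row per mode)
#'   and `ratios` (dual-relative-to-single and single-relative-to-dual
#'   quantities, including the pfAT ratio and SNR-ratio bounds).
#' @examples
#' compare_modes()$ratios$pfat_single_over_dual  # 4
#' @export
compare_modes <- function(single = NULL, dual = NULL, plan = NULL) {
  if (is.null(single))
    single <- list(cam = camera_config(mode = "single", shutter_width = 256L),
                   frame_time = 0.1)
  if (is.null(dual))
    dual <- list(cam = camera_config(mode = "dual", shutter_width = 256L),
                 frame_time = 0.025)
  for (side in list(single, dual))
    if (is.null(side$cam) || is.null(side$frame_time))
      stop("each mode needs `cam` and `frame_time`", call. = FALSE)
  if (single$cam$mode != "single" || dual$cam$mode != "dual")
    stop("camera modes must match their slots", call. = FALSE)

  row_of <- function(side) {
    sched <- shutter_schedule(side$cam, side$frame_time)
    data.frame(
      mode = side$cam$mode,
      frame_time_s = side$frame_time,
      frame_rate_fps = 1 / side$frame_time,
      row_exposure_s = sched$row_exposure,
      pfat_total_h = if (!is.null(plan))
        pfat_total(plan$n_stacks * plan$channels, plan$frames_per_stack,
                   side$frame_time)$hours else NA_real_)
  }
  tab <- rbind(row_of(single), row_of(dual))

  exp_ratio <- tab$row_exposure_s[2] / tab$row_exposure_s[1]
  ratios <- list(
    pfat_single_over_dual = single$frame_time / dual$frame_time,
    exposure_dual_over_single = exp_ratio,
    # SNR ratio dual/single lies between the read-noise-dominated limit
    # (= exposure ratio) and the shot-noise limit (= sqrt of it).
    snr_ratio_lower = min(exp_ratio, sqrt(exp_ratio)),
    snr_ratio_upper = max(exp_ratio, sqrt(exp_ratio)))
  structure(list(table = tab, ratios = ratios), class = "mode_comparison")
}

#' @export
print.mode_comparison <- function(x, ...) {
  cat("Acquisition mode comparison\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("  pfAT ratio (single/dual): %.3g\n",
              x$ratios$pfat_single_over_dual))
  cat(sprintf("  per-row exposure ratio (dual/single): %.3g\n",
              x$ratios$exposure_dual_over_single))
  cat(sprintf("  predicted SNR ratio (dual/single): %.4g - %.4g\n",
              x$ratios$snr_ratio_lower, x$ratios$snr_ratio_upper))
  invisible(x)
}

#' Export a tile plan as CSV
#'
#' @param plan A [plan_tiles()] result.
#' @param path Output CSV path. One row per tile position with the stack
#'   geometry columns repeated for convenience.
#' @export
write_plan_csv <- function(plan, path) {
  stopifnot(inherits(plan, "tile_plan"))
  df <- plan$positions
  df$frames_per_stack <- plan$frames_per_stack
  df$channels <- plan$channels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
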
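test_that("a box of one FOV and one pixel depth needs one tile, one frame", {
  sc <- immersion_scaling()
  px <- pixel_size(sc, 1.33)
  plan <- plan_tiles(c(2048 * px, 2048 * px, px), n = 1.33, overlap = 0,
                     tile_depth = px, scaling = sc)
  expect_identical(plan$n_stacks, 1L)
  expect_identical(plan$frames_per_stack, 1L)
  expect_identical(unname(unlist(plan$positions[1, ])), c(0, 0, 0))
})

test_that("frames per stack follow the axial step = pixel size rule", {
  plan <- plan_tiles(c(4200, 3300, 5500), n = 1.52, tile_depth = 140)
  px <- pixel_size(immersion_scaling(), 1.52)
  expect_identical(plan$frames_per_stack, as.integer(ceiling(140 / px)))
  expect_identical(plan$frames_per_stack, 377L)
  expect_error(plan_tiles(c(100, 100, 100), tile_depth = 0.1), "axial step")
})

test_that("tile grid equals a brute-force 1D covering on each axis", {
  brute_cover <- function(extent, tile, overlap) {
    if (extent <= tile) return(0)
    starts <- c(); s <- 0
    repeat {
      starts <- c(starts, s)
      if (s + tile >= extent) break
      s <- s + (1 - overlap) * tile
    }
    starts[length(starts)] <- extent - tile
    starts
  }
  sc <- immersion_scaling()
  for (overlap in c(0, 0.1, 0.25)) {
    plan <- plan_tiles(c(3000, 2500, 700), n = 1.33, overlap = overlap,
                       tile_depth = 140, scaling = sc)
    fov <- field_of_view(sc, 1.33)
    expect_equal(sort(unique(plan$positions$x)),
                 brute_cover(3000, fov, overlap))
    expect_equal(sort(unique(plan$positions$y)),
                 brute_cover(2500, fov, overlap))
    expect_equal(sort(unique(plan$positions$z)),
                 brute_cover(700, 140, overlap))
  }
})

test_that("the tile union covers the bounding box", {
  set.seed(71)
  plan <- plan_tiles(c(2600, 1900, 450), n = 1.4, overlap = 0.1,
                     tile_depth = 140)
  ts <- plan$tile_size
  pts <- cbind(runif(500, 0, 2600), runif(500, 0, 1900), runif(500, 0, 450))
  covered <- vapply(seq_len(nrow(pts)), function(i) {
    any(plan$positions$x <= pts[i, 1] &
          pts[i, 1] <= plan$positions$x + ts["x"] &
          plan$positions$y <= pts[i, 2] &
          pts[i, 2] <= plan$positions$y + ts["y"] &
          plan$positions$z <= pts[i, 3] &
          pts[i, 3] <= plan$positions$z + ts["z"])
  }, TRUE)
  expect_true(all(covered))
})

test_that("cumulative pfAT reproduces the printed forepaw total", {
  tot <- pfat_total(1672, 425, 0.025)
  expect_equal(tot$hours, 4.93)
  # the single-focus counterpart at 100 ms is four-fold
  expect_equal(pfat_total(1672, 425, 0.1)$seconds, 4 * tot$seconds)
  expect_equal(pfat_total(1, 1, 0.07)$seconds, 0.07)
  expect_equal(pfat_total(2 * 1672, 425, 0.025)$seconds, 2 * tot$seconds)
})

test_that("the timing budget components sum exactly to the total", {
  plan <- plan_tiles(c(2600, 1900, 450), n = 1.4, overlap = 0.1,
                     tile_depth = 140, channels = 2L)
  b <- total_imaging_time(plan, frame_time = 0.025, flyback = 0.0025,
                          stack_delay = 3)
  expect_identical(b$pfat_total_s + b$flyback_total_s + b$stack_delay_total_s,
                   b$total_imaging_time_s)
  b0 <- total_imaging_time(plan, frame_time = 0.025)
  expect_identical(b0$total_imaging_time_s, b0$pfat_total_s)
  expect_identical(b0$pfat_total_s,
                   plan$n_stacks * 2 * plan$frames_per_stack * 0.025)
})

test_that("dataset size arithmetic matches the printed tile/TB values", {
  one <- list(n_stacks = 1, channels = 1, frames_per_stack = 425,
              scaling = immersion_scaling())
  expect_equal(dataset_bytes(one) / 1e9, 3.57, tolerance = 0.01)
  stomach <- list(n_stacks = 2171, channels = 1, frames_per_stack = 386,
                  scaling = immersion_scaling())
  expect_equal(dataset_bytes(stomach) / 1e12, 7.03, tolerance = 0.01)
  none <- list(n_stacks = 0, channels = 1, frames_per_stack = 425,
               scaling = immersion_scaling())
  expect_identical(dataset_bytes(none), 0)
})

test_that("mode comparison reports the four-fold pfAT improvement", {
  cm <- compare_modes()
  expect_equal(cm$ratios$pfat_single_over_dual, 4)
  expect_equal(cm$table$frame_rate_fps[cm$table$mode == "dual"], 40)
  expect_equal(cm$table$frame_time_s[cm$table$mode == "single"], 0.1)
  expect_equal(cm$ratios$exposure_dual_over_single, 0.5)
  expect_equal(cm$ratios$snr_ratio_lower, 0.5)
  expect_equal(cm$ratios$snr_ratio_upper, 1 / sqrt(2))
  # identical configurations give unit ratios
  same <- list(cam = camera_config(mode = "dual", shutter_width = 64L),
               frame_time = 0.05)
  single_same <- list(cam = camera_config(mode = "single",
                                          shutter_width = 128L),
                      frame_time = 0.05)
  cm2 <- compare_modes(single_same, same)
  expect_equal(cm2$ratios$pfat_single_over_dual, 1)
  expect_error(compare_modes(single = list(frame_time = 0.1)), "needs")
})

test_that("pfAT ratio between modes is independent of the plan", {
  for (box in list(c(1000, 1000, 300), c(4200, 3300, 5500))) {
    plan <- plan_tiles(box, n = 1.52, tile_depth = 140)
    n_st <- plan$n_stacks * plan$channels
    r <- pfat_total(n_st, plan$frames_per_stack, 0.1)$seconds /
      pfat_total(n_st, plan$frames_per_stack, 0.025)$seconds
    expect_equal(r, 4)
  }
})

test_that("plan CSV export lists every tile position", {
  plan <- plan_tiles(c(2000, 1500, 300), n = 1.33, tile_depth = 140)
  f <- tempfile(fileext = ".csv")
  write_plan_csv(plan, f)
  df <- read.csv(f)
  expect_identical(nrow(df), plan$n_stacks)
  expect_true(all(c("x", "y", "z", "frames_per_stack") %in% names(df)))
})
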
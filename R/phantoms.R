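#' Random bead phantom
#'
#' Emulates sub-diffraction fluorescent beads (default 500 nm diameter, as
#' used for PSF calibration in agarose) at uniformly random positions inside
#' a rectangular volume, with an optional minimum pairwise separation
#' enforced by rejection sampling. Output is a pure function of the
#' parameters and the seed.
#'
#' @param extents Volume extents, µm: numeric length 3 `(x, y, z)`.
#' @param n_beads Number of beads (>= 0).
#' @param diameter Bead diameter, µm.
#' @param intensity Expected peak photoelectron rate per bead, e-/s at unit
#'   exposure; recycled to `n_beads`.
#' @param min_separation Minimum pairwise centre distance, µm.
#' @param background_rate Uniform background photoelectron rate, e-/s.
#' @param margin Keep-out margin from the volume faces, µm.
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling budget per bead.
#' @return An object of class `bead_phantom` with fields `positions`
#'   (n x 3 matrix, columns x/y/z, µm), `intensity`, `diameter`, `extents`,
#'   `background_rate`, `seed`.
#' @examples
#' ph <- bead_phantom(c(30, 30, 20), n_beads = 10, seed = 7)
#' nrow(ph$positions)
#' @export
bead_phantom <- function(extents, n_beads, diameter = 0.5,
                         intensity = 2e4, min_separation = 0,
                         background_rate = 0, margin = 2, seed = 1L,
                         max_tries = 200L) {
  if (!is.numeric(extents) || length(extents) != 3L || any(extents <= 0))
    stop("`extents` must be three positive lengths (x, y, z) in um",
         call. = FALSE)
  n_beads <- chk_count(n_beads, "n_beads", lower = 0L)
  chk_num(diameter, "diameter", lower = 0, strict_lower = TRUE)
  chk_num(min_separation, "min_separation", lower = 0)
  chk_num(background_rate, "background_rate", lower = 0)
  lo <- pmin(margin, extents / 4)
  hi <- extents - lo
  pos <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z")))
  if (n_beads > 0) {
    set.seed(derive_seed(seed, 1L))
    pos <- matrix(NA_real_, n_beads, 3,
                  dimnames = list(NULL, c("x", "y", "z")))
    for (i in seq_len(n_beads)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- lo + stats::runif(3) * (hi - lo)
        if (i == 1L || min_separation == 0) { ok <- TRUE } else {
          d2 <- rowSums((pos[seq_len(i - 1L), , drop = FALSE] -
                           matrix(cand, i - 1L, 3, byrow = TRUE))^2)
          ok <- all(d2 >= min_separation^2)
        }
        if (ok) { pos[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed)
        stop(sprintf(
          "could not place bead %d with min_separation = %g after %d tries",
          i, min_separation, max_tries), call. = FALSE)
    }
  }
  structure(
    list(positions = pos,
         intensity = rep_len(intensity, n_beads),
         diameter = diameter, extents = extents,
         background_rate = background_rate, seed = seed),
    class = "bead_phantom"
  )
}

#' @export
print.bead_phantom <- function(x, ...) {
  cat(sprintf("Bead phantom: %d beads (d = %g um) in %g x %g x %g um volume\n",
              nrow(x$positions), x$diameter,
              x$extents[1], x$extents[2], x$extents[3]))
  invisible(x)
}

# Stamp an additive separable Gaussian blob into `vol` (modified in place by
# the caller through the returned array).
add_blob <- function(vol, center, sigma, amplitude) {
  d <- dim(vol)
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, floor(center[a] - 4 * sigma[a]))
    hi <- min(d[a], ceiling(center[a] + 4 * sigma[a]))
    lo:hi
  })
  if (any(vapply(rng, length, 1L) == 0L)) return(vol)
  g <- lapply(1:3, function(a)
    exp(-(rng[[a]] - center[a])^2 / (2 * sigma[a]^2)))
  vol[rng[[1]], rng[[2]], rng[[3]]] <-
    vol[rng[[1]], rng[[2]], rng[[3]]] +
    amplitude * (outer(g[[1]], g[[2]]) %o% g[[3]])
  vol
}

#' Synthetic low-resolution tissue tile
#'
#' Generates one small 3D tile of the kind produced by a low-resolution
#' pre-scan of cleared tissue. `"informative"` tiles contain tissue-like
#' structure — soft Gaussian blobs (cell clusters) and random-walk filaments
#' (vessels / neurites) — over a flat background; `"empty"` tiles contain
#' background and read noise only (a media-only volume). Class contrast is
#' expressed in units of the noise standard deviation: structure amplitudes
#' are about `contrast * noise` counts, so at `contrast -> 0` the two kinds
#' become statistically indistinguishable.
#'
#' @param kind `"informative"` or `"empty"`.
#' @param shape Tile dimensions `(rows, cols, planes)`.
#' @param blob_count,filament_count Number of structures; `NULL` draws a
#'   count at random (2-6 blobs, 0-2 filaments) for dataset variety.
#' @param contrast Structure amplitude in noise-sd units (> 0 for
#'   informative tiles).
#' @param noise Read-noise standard deviation, counts.
#' @param background Background offset, counts.
#' @param seed Integer seed; the tile is a pure function of (parameters,
#'   seed).
#' @return A 3D numeric array with attributes `kind` and `seed`.
#' @export
tissue_tile <- function(kind = c("informative", "empty"),
                        shape = c(128L, 128L, 8L),
                        blob_count = NULL, filament_count = NULL,
                        contrast = 10, noise = 2, background = 100,
                        seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(shape) || length(shape) != 3L || any(shape < 1))
    stop("`shape` must be three positive dimensions", call. = FALSE)
  shape <- as.integer(shape)
  chk_num(noise, "noise", lower = 0)
  chk_num(background, "background", lower = 0)
  if (kind == "informative")
    chk_num(contrast, "contrast", lower = 0, strict_lower = TRUE)

  set.seed(derive_seed(seed, 2L))
  vol <- array(0, dim = shape)

  if (kind == "informative") {
    nb <- if (is.null(blob_count)) sample(2:6, 1L) else
      chk_count(blob_count, "blob_count", lower = 0L)
    nf <- if (is.null(filament_count)) sample(0:2, 1L) else
      chk_count(filament_count, "filament_count", lower = 0L)
    amp <- contrast * noise
    # one extended tissue mass: a pre-scan tile crossing the tissue boundary
    # always contains structure at the scale of many pixels
    if (nb > 0) {
      center <- c(stats::runif(2, 0.25, 0.75) * shape[1:2],
                  stats::runif(1, 1, shape[3]))
      sigma <- c(stats::runif(2, 0.06, 0.14) * shape[1:2],
                 stats::runif(1, 1, shape[3]))
      vol <- add_blob(vol, center, sigma, amp * stats::runif(1, 0.8, 1.5))
    }
    for (b in seq_len(max(0L, nb - 1L))) {
      center <- c(stats::runif(2, 0.15, 0.85) * shape[1:2],
                  stats::runif(1, 1, shape[3]))
      sigma <- c(stats::runif(2, 2, 6), stats::runif(1, 0.8, 2))
      vol <- add_blob(vol, center, sigma, amp * stats::runif(1, 0.8, 1.5))
    }
    for (f in seq_len(nf)) {
      pt <- c(stats::runif(2, 0.2, 0.8) * shape[1:2],
              stats::runif(1, 1, shape[3]))
      ang <- stats::runif(1, 0, 2 * pi)
      n_steps <- 30L
      for (s in seq_len(n_steps)) {
        ang <- ang + stats::rnorm(1, 0, 0.3)
        pt <- pt + c(2 * cos(ang), 2 * sin(ang), stats::rnorm(1, 0, 0.2))
        if (any(pt[1:2] < 3) || any(pt[1:2] > shape[1:2] - 2)) break
        pt[3] <- min(max(pt[3], 1), shape[3])
        vol <- add_blob(vol, pt, c(1.5, 1.5, 0.8),
                        amp * stats::runif(1, 0.6, 1.0))
      }
    }
  }

  tile <- background + vol + stats::rnorm(length(vol), 0, noise)
  tile <- array(tile, dim = shape)
  attr(tile, "kind") <- kind
  attr(tile, "seed") <- seed
  tile
}

#' Labelled synthetic tile dataset
#'
#' Generates a balanced, deterministically shuffled two-class dataset of
#' synthetic tissue tiles for triage training and evaluation. Informative
#' tiles are labelled 1, empty (media-only) tiles 0. With the default
#' `n_per_class = 2080` the dataset has 4,160 items, so an 80/20
#' train/validation split gives 3,328 / 832 images.
#'
#' @param n_per_class Tiles per class.
#' @param tile_shape Tile dimensions `(rows, cols, planes)`.
#' @param contrast,noise,background Passed to [tissue_tile()].
#' @param store `"mip"` keeps the axial maximum-intensity projection of each
#'   tile (sufficient for both triage paths and 8x lighter); `"stack"` keeps
#'   full 3D tiles.
#' @param seed Integer seed.
#' @return An object of class `tile_dataset`: `tiles` (list), `labels`
#'   (integer 0/1), `kinds`, `seeds`, and the generation parameters.
#' @examples
#' ds <- make_tile_dataset(n_per_class = 5, seed = 3)
#' table(ds$labels)
#' @export
make_tile_dataset <- function(n_per_class = 2080L,
                              tile_shape = c(128L, 128L, 8L),
                              contrast = 10, noise = 2, background = 100,
                              store = c("mip", "stack"), seed = 1L) {
  n_per_class <- chk_count(n_per_class, "n_per_class")
  store <- match.arg(store)
  n_total <- 2L * n_per_class
  kinds <- rep(c("informative", "empty"), each = n_per_class)
  labels <- rep(c(1L, 0L), each = n_per_class)
  tile_seeds <- derive_seed(seed, 100L + seq_len(n_total))
  tiles <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    t3 <- tissue_tile(kinds[i], shape = tile_shape, contrast = contrast,
                      noise = noise, background = background,
                      seed = tile_seeds[i])
    tiles[[i]] <- if (store == "mip") mip(t3, axis = 3L) else t3
  }
  set.seed(derive_seed(seed, 3L))
  ord <- sample.int(n_total)
  structure(
    list(tiles = tiles[ord], labels = labels[ord], kinds = kinds[ord],
         seeds = tile_seeds[ord], n_per_class = n_per_class,
         tile_shape = as.integer(tile_shape), contrast = contrast,
         noise = noise, background = background, store = store, seed = seed),
    class = "tile_dataset"
  )
}

#' @export
print.tile_dataset <- function(x, ...) {
  cat(sprintf(
    "Tile dataset: %d tiles (%d per class), %s storage, contrast %g\n",
    length(x$tiles), x$n_per_class, x$store, x$contrast))
  invisible(x)
}

#' Write a dataset manifest CSV
#'
#' One row per tile: index, label, kind, seed. If `tile_dir` is given, each
#' tile is also written as a 16-bit TIFF and the manifest records its path.
#'
#' @param dataset A [make_tile_dataset()] result.
#' @param path Manifest CSV path.
#' @param tile_dir Optional directory for per-tile TIFF output.
#' @export
write_dataset_manifest <- function(dataset, path, tile_dir = NULL) {
  stopifnot(inherits(dataset, "tile_dataset"))
  n <- length(dataset$tiles)
  paths <- rep(NA_character_, n)
  if (!is.null(tile_dir)) {
    dir.create(tile_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n)) {
      paths[i] <- file.path(tile_dir, sprintf("tile_%05d.tif", i))
      arr <- dataset$tiles[[i]]
      if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
      write_stack(arr, paths[i])
    }
  }
  utils::write.csv(
    data.frame(index = seq_len(n), label = dataset$labels,
               kind = dataset$kinds, seed = dataset$seeds, path = paths),
    path, row.names = FALSE)
  invisible(path)
}
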
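#' Intensity-triage parameters
#'
#' Parameters of the intensity-based informative-tile classifier: the MIP of
#' each tile is smoothed by two uniform (box) filters, their difference
#' suppresses the slowly varying background, and the score is the percentage
#' of difference pixels strictly above an absolute threshold. Tiles scoring
#' below the cutoff are non-informative.
#'
#' Even-sized box kernels have no centre pixel; the convention here is that
#' the kernel origin is offset toward the lower index (a k-wide window spans
#' `floor(k/2)` pixels below and `k - 1 - floor(k/2)` above), with reflective
#' (edge-duplicating) padding. This convention is fixed so that the fast
#' summed-area implementation and any direct reimplementation agree exactly.
#'
#' @param kernel_small,kernel_large Box filter sizes, pixels (small < large).
#' @param intensity_threshold Absolute threshold on the difference image.
#' @param informative_cutoff Score cutoff, percent, in (0, 100); a tile is
#'   informative iff its score is >= the cutoff.
#' @return An object of class `triage_params`.
#' @export
triage_params <- function(kernel_small = 20L, kernel_large = 40L,
                          intensity_threshold = 2.5,
                          informative_cutoff = 0.1) {
  kernel_small <- chk_count(kernel_small, "kernel_small")
  kernel_large <- chk_count(kernel_large, "kernel_large")
  if (kernel_small >= kernel_large)
    stop("kernel_small must be smaller than kernel_large", call. = FALSE)
  chk_num(intensity_threshold, "intensity_threshold")
  chk_num(informative_cutoff, "informative_cutoff", lower = 0, upper = 100,
          strict_lower = TRUE)
  if (informative_cutoff >= 100)
    stop("informative_cutoff must be < 100", call. = FALSE)
  structure(
    list(kernel_small = kernel_small, kernel_large = kernel_large,
         intensity_threshold = intensity_threshold,
         informative_cutoff = informative_cutoff),
    class = "triage_params"
  )
}

# Uniform (mean) box filter with the package's even-kernel and padding
# conventions, via a summed-area table on the reflectively padded image.
box_smooth <- function(img, k) {
  stopifnot(is.matrix(img))
  lo <- k %/% 2L
  hi <- k - 1L - lo
  nr <- nrow(img); nc <- ncol(img)
  ridx <- c(if (lo > 0) pmax(lo:1, 1L), 1:nr, if (hi > 0) pmin(nr:(nr - hi + 1L), nr))
  cidx <- c(if (lo > 0) pmax(lo:1, 1L), 1:nc, if (hi > 0) pmin(nc:(nc - hi + 1L), nc))
  pad <- img[ridx, cidx, drop = FALSE]
  # summed-area table with a zero border
  S <- matrix(0, nrow(pad) + 1L, ncol(pad) + 1L)
  S[-1, -1] <- apply(apply(pad, 2, cumsum), 1, cumsum) |> t()
  i1 <- 1:nr; i2 <- i1 + k
  j1 <- 1:nc; j2 <- j1 + k
  (S[i2, j2] - S[i2, j1] - S[i1, j2] + S[i1, j1]) / (k * k)
}

#' Intensity-based informative-tile score
#'
#' For a 3D tile: (1) take the MIP along the axial dimension; (2) smooth the
#' MIP with uniform box filters of `kernel_small` and `kernel_large` pixels;
#' (3) subtract the large-kernel image from the small-kernel image to remove
#' background; (4) return the percentage of pixels in the difference image
#' strictly above `intensity_threshold`. A 2D matrix is accepted as an
#' already-projected MIP. Adding a constant to every pixel does not change
#' the score (both smoothed images shift equally), but the score is not
#' scale-invariant: the threshold is absolute.
#'
#' @param tile A 3D array (tile stack) or 2D matrix (MIP).
#' @param params A [triage_params()].
#' @return Score in percent of pixels.
#' @export
intensity_score <- function(tile, params = triage_params()) {
  stopifnot(inherits(params, "triage_params"))
  m <- if (is.matrix(tile)) tile else mip(tile, axis = 3L)
  if (nrow(m) < params$kernel_large || ncol(m) < params$kernel_large)
    stop(sprintf("tile (%d x %d) smaller than the large kernel (%d)",
                 nrow(m), ncol(m), params$kernel_large), call. = FALSE)
  diff_img <- box_smooth(m, params$kernel_small) -
    box_smooth(m, params$kernel_large)
  100 * sum(diff_img > params$intensity_threshold) / length(diff_img)
}

#' Classify tiles with the intensity recipe
#'
#' @param tiles A [make_tile_dataset()] object or a list of tiles (3D arrays
#'   or 2D MIPs).
#' @param params A [triage_params()].
#' @return A data frame of class `triage_result`: `id`, `score` (percent),
#'   `label` (`"informative"` iff score >= `informative_cutoff`, else
#'   `"non-informative"`).
#' @export
classify_intensity <- function(tiles, params = triage_params()) {
  stopifnot(inherits(params, "triage_params"))
  tl <- if (inherits(tiles, "tile_dataset")) tiles$tiles else tiles
  if (!is.list(tl)) tl <- list(tl)
  scores <- vapply(tl, intensity_score, numeric(1), params = params)
  out <- data.frame(
    id = seq_along(scores),
    score = scores,
    label = ifelse(scores >= params$informative_cutoff,
                   "informative", "non-informative"))
  class(out) <- c("triage_result", class(out))
  out
}

#' ROC curve and AUC
#'
#' Standard threshold sweep over the scores of a binary problem, with the
#' area under the curve computed by the trapezoid rule. Ties in the scores
#' are handled by grouping (one ROC vertex per distinct score).
#'
#' @param labels True class labels: 0/1 (or logical). Both classes must be
#'   present.
#' @param scores Numeric scores, higher = more likely positive.
#' @return An object of class `roc_result`: `points` (data frame `fpr`,
#'   `tpr`, starting at (0,0) and ending at (1,1)) and `auc`.
#' @export
roc_curve <- function(labels, scores) {
  labels <- as.integer(as.logical(labels) | labels == 1)
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length", call. = FALSE)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab == 1L)
  fp <- cumsum(lab == 0L)
  last <- c(diff(sc) != 0, TRUE)  # one vertex per distinct score
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: %d vertices, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "false-positive rate", ylab = "true-positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  graphics::legend("bottomright", sprintf("AUC = %.4f", x$auc), bty = "n")
  invisible(x)
}

#' Informative-tile coordinate map
#'
#' Filters a tile grid down to the stage positions whose tiles were labelled
#' informative, preserving acquisition order. This map is what would be fed
#' back to the microscope to restrict high-resolution imaging to the tissue
#' boundary.
#'
#' @param tile_grid A data frame of stage positions, one row per tile (any
#'   columns, typically `x`, `y`, `z` in µm), in acquisition order.
#' @param results A `triage_result` data frame (or any data frame with a
#'   `label` column), one row per grid position.
#' @param file Optional CSV output path.
#' @return The informative subset of `tile_grid` (same columns, original
#'   order).
#' @export
coordinate_map <- function(tile_grid, results, file = NULL) {
  stopifnot(is.data.frame(tile_grid))
  if (nrow(tile_grid) != nrow(results))
    stop(sprintf("grid has %d positions but results has %d rows",
                 nrow(tile_grid), nrow(results)), call. = FALSE)
  keep <- results$label == "informative"
  out <- tile_grid[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
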
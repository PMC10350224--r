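#' Write a stack as a multi-page 16-bit TIFF
#'
#' Counts are written losslessly as 16-bit pages (one page per plane). A
#' plain-text YAML sidecar (`<path>.yml`) records the voxel size and
#' metadata so that [read_stack()] can round-trip the object.
#'
#' @param stack A `sim_stack` or 3D numeric array of counts in
#'   `[0, 65535]`.
#' @param path Output TIFF path.
#' @param voxel_size Voxel size `(row, col, plane)`, µm; taken from a
#'   `sim_stack` when omitted.
#' @param metadata Named list merged into the sidecar (e.g. mode, frame
#'   time, seed, config hash).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, voxel_size = NULL, metadata = list()) {
  if (inherits(stack, "sim_stack")) {
    if (is.null(voxel_size)) voxel_size <- stack$voxel_size
    metadata <- utils::modifyList(stack$metadata, metadata)
    x <- stack$counts
  } else {
    x <- stack
  }
  stopifnot(is.array(x), length(dim(x)) == 3L)
  if (is.null(voxel_size)) voxel_size <- c(1, 1, 1)
  if (any(x < 0) || any(x > 65535))
    stop("counts out of 16-bit range", call. = FALSE)
  pages <- lapply(seq_len(dim(x)[3]), function(k) x[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- list(
    voxel_size_um = as.numeric(voxel_size),
    dim = as.integer(dim(x)),
    metadata = metadata)
  yaml::write_yaml(sidecar, paste0(path, ".yml"), precision = 12L)
  invisible(path)
}

#' Read a multi-page 16-bit TIFF stack
#'
#' Reads integer counts losslessly and, when present, the YAML sidecar with
#' voxel size and metadata. Files with a bit depth other than 16 are
#' rejected explicitly rather than silently promoted.
#'
#' @param path TIFF path written by [write_stack()] (or any 16-bit
#'   multi-page TIFF).
#' @return A list of class `stack_file`: `counts` (3D integer array),
#'   `voxel_size` (µm; `NA` when no sidecar), `metadata`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
    error = function(e)
      stop(sprintf("unreadable TIFF %s: %s", path, conditionMessage(e)),
           call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample")
  if (!is.null(bits) && bits != 16L)
    stop(sprintf(
      "%s is %d-bit; this reader handles 16-bit stacks only - convert explicitly",
      path, bits), call. = FALSE)
  d1 <- dim(pages[[1]])
  counts <- array(0L, dim = c(d1[1], d1[2], length(pages)))
  for (k in seq_along(pages)) {
    if (!identical(dim(pages[[k]])[1:2], d1[1:2]))
      stop(sprintf("truncated or inconsistent TIFF %s at page %d", path, k),
           call. = FALSE)
    counts[, , k] <- pages[[k]]
  }
  voxel_size <- c(NA_real_, NA_real_, NA_real_)
  metadata <- list()
  sidecar_path <- paste0(path, ".yml")
  if (file.exists(sidecar_path)) {
    sc <- yaml::read_yaml(sidecar_path)
    if (!is.null(sc$voxel_size_um)) voxel_size <- as.numeric(sc$voxel_size_um)
    if (!is.null(sc$metadata)) metadata <- sc$metadata
  }
  structure(list(counts = counts, voxel_size = voxel_size,
                 metadata = metadata),
            class = "stack_file")
}

# ---- configuration ---------------------------------------------------------

default_config <- function() {
  list(
    instrument = list(
      sensor_pitch = 6.5,
      n_rows = 2048L,
      n_cols = 2048L,
      reference_magnification = 15.28,
      reference_index = 1.33,
      shutter_width = 256L,
      offset_counts = 100,
      read_noise_counts = 2,
      conversion_gain = 0.46,
      single_frame_time = 0.1,
      dual_frame_time = 0.025,
      flyback_fraction = 0.1,
      mirror_offset = 100,
      axial_gain = NULL,
      lfa_travel_range = 10000,
      lfa_repeatability = 0.05,
      lfa_response_time = 0.003
    ),
    beam = list(
      wavelength = 0.488,
      waist_radius = 0.5,
      immersion_index = 1.33
    ),
    phantom = list(
      tile_rows = 128L,
      tile_cols = 128L,
      tile_planes = 8L,
      n_per_class = 2080L,
      contrast = 10,
      noise = 2,
      background = 100
    ),
    triage = list(
      kernel_small = 20L,
      kernel_large = 40L,
      intensity_threshold = 2.5,
      informative_cutoff = 0.1,
      n_blocks = 3L,
      filters = c(8L, 16L, 32L),
      input_size = 32L,
      batch_size = 32L,
      train_fraction = 0.8,
      patience_epochs = 10L,
      max_epochs = 50L,
      learning_rate = 1e-3,
      probability_threshold = 0.5
    ),
    planner = list(
      overlap = 0.1,
      tile_depth = 140,
      channels = 1L,
      stack_delay = 0,
      immersion_index = 1.52
    ),
    seed = 1L,
    output_dir = ".",
    verbosity = "info"
  )
}

merge_validate <- function(defaults, user, path = character()) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    full <- vapply(unknown, function(nm) paste(c(path, nm), collapse = "$"),
                   character(1))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(full, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_validate(defaults[[nm]], as.list(user[[nm]]),
                                       c(path, nm))
    } else if (is.null(user[[nm]])) {
      defaults[nm] <- list(NULL)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  errs <- character()
  add <- function(msg) errs <<- c(errs, msg)
  ins <- cfg$instrument
  if (ins$n_rows %% 2L != 0L)
    add("instrument$n_rows must be even (dual mode uses two half-frame shutters)")
  if (ins$sensor_pitch <= 0) add("instrument$sensor_pitch must be > 0")
  if (ins$reference_magnification <= 0)
    add("instrument$reference_magnification must be > 0")
  if (ins$reference_index < 1) add("instrument$reference_index must be >= 1")
  if (ins$shutter_width < 1 || ins$shutter_width > ins$n_rows / 2)
    add("instrument$shutter_width must be in [1, n_rows/2] to be valid in both modes")
  if (ins$single_frame_time <= 0 || ins$dual_frame_time <= 0)
    add("frame times must be > 0")
  if (ins$flyback_fraction < 0)
    add("instrument$flyback_fraction must be >= 0")
  if (cfg$beam$wavelength <= 0) add("beam$wavelength must be > 0")
  if (cfg$beam$waist_radius <= 0) add("beam$waist_radius must be > 0")
  if (cfg$beam$immersion_index < 1) add("beam$immersion_index must be >= 1")
  tr <- cfg$triage
  if (tr$kernel_small >= tr$kernel_large)
    add("triage$kernel_small must be < triage$kernel_large")
  if (tr$informative_cutoff <= 0 || tr$informative_cutoff >= 100)
    add("triage$informative_cutoff must be in (0, 100)")
  if (tr$input_size %% 2^tr$n_blocks != 0)
    add("triage$input_size must be divisible by 2^n_blocks")
  if (tr$probability_threshold < 0 || tr$probability_threshold > 1)
    add("triage$probability_threshold must be in [0, 1]")
  pl <- cfg$planner
  if (pl$overlap < 0 || pl$overlap > 0.9)
    add("planner$overlap must be in [0, 0.9]")
  if (pl$channels < 1) add("planner$channels must be >= 1")
  if (!cfg$verbosity %in% c("quiet", "info", "debug"))
    add("verbosity must be one of quiet/info/debug")
  if (length(errs))
    stop(paste(c("invalid configuration:",
                 paste0("  - ", errs)), collapse = "\n"), call. = FALSE)
  invisible(cfg)
}

#' Load a run configuration
#'
#' Reads a plain-text YAML configuration, applies the documented defaults
#' for every key not present, rejects unknown keys (itemized), and
#' validates every field against its module's constraints. An empty file
#' yields the full default configuration.
#'
#' @param path Path to a YAML configuration file, or `NULL` for defaults.
#' @return An object of class `run_config` (a nested list with sections
#'   `instrument`, `beam`, `phantom`, `triage`, `planner`, plus `seed`,
#'   `output_dir`, `verbosity`), with attribute `hash` (MD5 of the resolved
#'   configuration).
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop(sprintf("configuration file not found: %s", path), call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  cfg <- merge_validate(default_config(), user)
  validate_config(cfg)
  structure(cfg, class = "run_config", hash = config_hash(cfg))
}

#' Save a run configuration
#'
#' @param config A `run_config` (or compatible nested list).
#' @param path Output YAML path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Hash of a resolved configuration
#'
#' MD5 digest of the canonical YAML rendering; recorded in output sidecars
#' so every output file can be traced to the configuration that produced it.
#'
#' @param config A `run_config` or nested list.
#' @return A hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration (hash", substr(attr(x, "hash"), 1, 8), ")\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}
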
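# Internal validation and numeric helpers shared across modules.

chk_num <- function(x, name, lower = -Inf, upper = Inf, finite = TRUE,
                    strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single numeric value", name), call. = FALSE)
  if (finite && !is.finite(x))
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  if (strict_lower) {
    if (x <= lower)
      stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  } else if (x < lower) {
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  }
  if (x > upper)
    stop(sprintf("`%s` must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

chk_count <- function(x, name, lower = 1L) {
  chk_num(x, name, lower = lower)
  if (x != round(x))
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  invisible(as.integer(x))
}

# Round to nearest integer, ties away from zero (differs from IEC round half
# even used by base::round).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# FWHM of a Gaussian from its standard deviation and back.
FWHM_FACTOR <- 2 * sqrt(2 * log(2))

sigma_to_fwhm <- function(sigma) FWHM_FACTOR * sigma
fwhm_to_sigma <- function(fwhm) fwhm / FWHM_FACTOR

# Derive a stream-specific integer seed below 2^31 from a base seed.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}
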
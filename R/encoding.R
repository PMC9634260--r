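#' Image-to-drive encoder configuration
#'
#' Grayscale pixels are mapped to per-input-neuron drive. In
#' `"constant_current"` mode (the default) the drive is a constant current
#' proportional to the pixel value, so each input neuron fires periodically
#' at a pixel-dependent rate; any constant bias is added by the input
#' neuron's own parameters, not here. In `"poisson"` mode each neuron emits
#' an independent Bernoulli spike train with per-step probability
#' `rate * dt`, rate proportional to the pixel value.
#'
#' @param pixel_max Full-scale pixel value (255 for 8-bit images, 1 for
#'   floating-point images in `[0, 1]`).
#' @param current_scale Drive produced by a full-scale pixel.
#' @param mode `"constant_current"` or `"poisson"`.
#' @param poisson_max_rate Firing rate in Hz of a full-scale pixel in
#'   Poisson mode.
#' @param noise_sigma Standard deviation of additive zero-mean Gaussian
#'   drive noise (0 disables).
#'
#' @return An object of class `"encoder_config"`.
#' @export
encoder_config <- function(pixel_max = 255, current_scale = 1,
                           mode = c("constant_current", "poisson"),
                           poisson_max_rate = 60, noise_sigma = 0) {
  mode <- match.arg(mode)
  if (pixel_max <= 0) stop("`pixel_max` must be positive", call. = FALSE)
  if (current_scale <= 0) stop("`current_scale` must be positive", call. = FALSE)
  if (poisson_max_rate <= 0) stop("`poisson_max_rate` must be positive", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be non-negative", call. = FALSE)
  structure(
    list(pixel_max = pixel_max, current_scale = current_scale, mode = mode,
         poisson_max_rate = poisson_max_rate, noise_sigma = noise_sigma),
    class = "encoder_config"
  )
}

#' Encode pixels as constant input currents
#'
#' `drive_i = current_scale * pixels_i / pixel_max`. Deterministic.
#'
#' @param pixels Numeric vector or matrix of pixel intensities in
#'   `[0, pixel_max]` (a matrix is flattened column-major).
#' @param cfg An [encoder_config()].
#' @param label Optional class label attached to the sample.
#' @param duration Presentation duration in ms.
#'
#' @return An object of class `"encoded_sample"` with fields `drive`
#'   (constant current vector), `label` and `duration`.
#' @export
encode_constant_current <- function(pixels, cfg, label = NA, duration = 350) {
  pixels <- as.numeric(pixels)
  if (any(pixels < 0)) stop("negative pixel values", call. = FALSE)
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  structure(
    list(drive = cfg$current_scale * pixels / cfg$pixel_max,
         raster = NULL, label = label, duration = duration),
    class = "encoded_sample"
  )
}

#' Encode pixels as Poisson spike rasters
#'
#' Each input neuron emits independent Bernoulli(`rate_i * dt`) spikes per
#' step, with `rate_i = poisson_max_rate * pixels_i / pixel_max`.
#' Reproducible under a fixed RNG state (`set.seed()` before calling).
#'
#' @inheritParams encode_constant_current
#' @param duration Presentation duration in ms (multiple of `dt`).
#' @param dt Timestep in ms.
#'
#' @return An `"encoded_sample"` whose `raster` field is a logical
#'   neurons x timesteps matrix; `drive` is `NULL`.
#' @export
encode_poisson <- function(pixels, duration, dt, cfg, label = NA) {
  pixels <- as.numeric(pixels)
  if (any(pixels < 0)) stop("negative pixel values", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  n_steps <- round(duration / dt)
  if (abs(n_steps * dt - duration) > 1e-9) {
    stop("`duration` must be a multiple of `dt`", call. = FALSE)
  }
  rate <- cfg$poisson_max_rate * pixels / cfg$pixel_max   # Hz
  p <- rate * dt / 1000
  if (any(p > 1)) {
    stop("rate * dt exceeds 1 spike per step: undersampled; reduce dt",
         call. = FALSE)
  }
  raster <- matrix(stats::runif(length(pixels) * n_steps) < p,
                   nrow = length(pixels), ncol = n_steps)
  structure(
    list(drive = NULL, raster = raster, label = label, duration = duration),
    class = "encoded_sample"
  )
}

#' Add zero-mean Gaussian noise to a drive vector
#'
#' Models noisy analog input currents; the expectation of the drive is
#' unchanged.
#'
#' @param drive Numeric drive vector.
#' @param noise_sigma Noise standard deviation (>= 0).
#'
#' @return The perturbed drive vector.
#' @export
inject_gaussian_noise <- function(drive, noise_sigma) {
  if (noise_sigma < 0) stop("`noise_sigma` must be non-negative", call. = FALSE)
  if (noise_sigma == 0) return(drive)
  drive + stats::rnorm(length(drive), mean = 0, sd = noise_sigma)
}
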
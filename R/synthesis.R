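# Seeded generator of synthetic circle phantoms with ground-truth
# boundaries. Two intensity classes emulate the kinds of cardiac-MRI
# slices the detector targets: "low" phantoms are dark with high
# foreground/background contrast, "high" phantoms are brighter with low
# contrast (hence lower gradient but higher global SNR). Ground truth is
# the 1-pixel inner boundary of the shape, captured before blur and
# noise are applied.

#' Phantom specification
#'
#' Parameters of one synthetic circle phantom. Ranges (radius, blur,
#' noise) are sampled per phantom from the given seed.
#'
#' @param intensity_class \code{"low"} (background ~10, foreground ~200)
#'   or \code{"high"} (background ~120, foreground ~180).
#' @param size Image side length in pixels.
#' @param radius_range Two-element range the circle radius is drawn from.
#' @param center_jitter Maximum displacement of the center from the image
#'   middle, per axis.
#' @param sigma_blur_range Range of the Gaussian blur applied after
#'   rasterization.
#' @param sigma_noise_range Range of the additive Gaussian noise standard
#'   deviation.
#' @param distort If \code{TRUE}, the circle becomes an ellipse with a
#'   sinusoidal radial perturbation.
#' @param distortion_amplitude Perturbation amplitude as a fraction of the
#'   radius.
#' @param seed Integer seed; fully determines the phantom.
#' @return A list of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(intensity_class = c("low", "high"), size = 128L,
                         radius_range = c(20, 45), center_jitter = 6,
                         sigma_blur_range = c(0.5, 1.5),
                         sigma_noise_range = c(2, 8),
                         distort = FALSE, distortion_amplitude = 0.1,
                         seed = 1L) {
  intensity_class <- match.arg(intensity_class)
  stopifnot(size >= 16, length(radius_range) == 2L,
            radius_range[1L] > 0, diff(radius_range) >= 0,
            center_jitter >= 0, distortion_amplitude >= 0)
  # worst case: eccentricity and sinusoidal lobe peak aligned
  max_extent <- max(radius_range) * (1 + 2 * distortion_amplitude) +
    center_jitter
  if (max_extent > size / 2 - 1) {
    stop("circle could exit the frame; shrink radius_range or center_jitter",
         call. = FALSE)
  }
  structure(list(intensity_class = intensity_class, size = as.integer(size),
                 radius_range = radius_range, center_jitter = center_jitter,
                 sigma_blur_range = sigma_blur_range,
                 sigma_noise_range = sigma_noise_range,
                 distort = isTRUE(distort),
                 distortion_amplitude = distortion_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

class_levels <- function(intensity_class) {
  if (intensity_class == "low") c(background = 10, foreground = 200)
  else c(background = 120, foreground = 180)
}

#' Generate one synthetic circle phantom
#'
#' Rasterizes a filled circle (or a distorted ellipse) at the class's
#' intensity levels, captures the 1-pixel inner boundary of the clean
#' shape as ground truth, then degrades the image with Gaussian blur and
#' additive Gaussian noise clipped to \[0, 255\]. Deterministic in the
#' spec's seed.
#'
#' @param spec A [phantom_spec()] object.
#' @return A [labeled_sample()]: \code{image} (degraded phantom) and
#'   \code{truth} (binary boundary map).
#' @export
make_circle_image <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  n <- spec$size
  radius <- stats::runif(1, spec$radius_range[1L], spec$radius_range[2L])
  cx <- (n + 1) / 2 + stats::runif(1, -spec$center_jitter, spec$center_jitter)
  cy <- (n + 1) / 2 + stats::runif(1, -spec$center_jitter, spec$center_jitter)
  sigma_blur <- stats::runif(1, spec$sigma_blur_range[1L], spec$sigma_blur_range[2L])
  sigma_noise <- stats::runif(1, spec$sigma_noise_range[1L], spec$sigma_noise_range[2L])
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  dx <- cols - cx; dy <- rows - cy
  dist <- sqrt(dx^2 + dy^2)
  if (spec$distort) {
    theta <- atan2(dy, dx)
    ecc <- stats::runif(1, 0, spec$distortion_amplitude)
    lobes <- sample(3:5, 1L)
    phase <- stats::runif(1, 0, 2 * pi)
    r_theta <- radius * (1 + ecc * cos(2 * theta) +
                         spec$distortion_amplitude * sin(lobes * theta + phase))
  } else {
    r_theta <- radius
  }
  mask <- dist <= r_theta
  lv <- class_levels(spec$intensity_class)
  image <- matrix(lv["background"], n, n)
  image[mask] <- lv["foreground"]
  # ground truth: mask pixels with a 4-neighbor outside the mask
  m <- mask * 1
  interior <- shift_replicate(m, 1L, 0L) * shift_replicate(m, -1L, 0L) *
    shift_replicate(m, 0L, 1L) * shift_replicate(m, 0L, -1L)
  truth <- matrix(as.numeric(mask & interior == 0), n, n)
  if (sigma_blur > 0) image <- gaussian_prefilter(image, sigma_blur)
  noise_seed <- spec$seed + 1000003L
  image <- inject_noise(image, sigma_noise, seed = noise_seed)
  labeled_sample(image, truth)
}

#' Add Gaussian noise to an image
#'
#' Adds independent zero-mean Gaussian noise of standard deviation
#' \code{sigma_noise} and clips to \[0, 255\]. \code{sigma_noise = 0}
#' returns the input unchanged.
#'
#' @param image Numeric matrix.
#' @param sigma_noise Non-negative standard deviation.
#' @param seed Optional integer seed for a reproducible noise field.
#' @return Degraded matrix of the same dimensions.
#' @export
inject_noise <- function(image, sigma_noise, seed = NULL) {
  check_image(image, min_dim = 1L)
  if (sigma_noise < 0) stop("'sigma_noise' must be non-negative", call. = FALSE)
  if (sigma_noise == 0) return(image)
  if (!is.null(seed)) set.seed(seed)
  out <- image + stats::rnorm(length(image), 0, sigma_noise)
  pmin(pmax(out, 0), 255)
}

#' Generate a synthetic optimization set
#'
#' Produces \code{n} phantoms of one intensity class with per-sample seeds
#' derived from a master seed; radius, center, blur, noise and the
#' distortion flag vary across samples (about 30% of phantoms are
#' distorted).
#'
#' @param n Number of phantoms (default 20).
#' @param intensity_class \code{"low"} or \code{"high"}.
#' @param master_seed Integer seed for the whole set.
#' @param ... Further arguments passed to [phantom_spec()].
#' @return List of [labeled_sample()] objects.
#' @export
make_optimization_set <- function(n = 20L, intensity_class = c("low", "high"),
                                  master_seed = 1L, ...) {
  intensity_class <- match.arg(intensity_class)
  stopifnot(n >= 1)
  set.seed(master_seed)
  seeds <- sample.int(2^31 - 10L, n)
  distorted <- stats::runif(n) < 0.3
  lapply(seq_len(n), function(i) {
    make_circle_image(phantom_spec(intensity_class = intensity_class,
                                   distort = distorted[i],
                                   seed = seeds[i], ...))
  })
}
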
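# Quantitative evaluation: Dice overlap between edge maps (the
# optimization fitness), PSNR and SSIM on {0,255}-scaled binary maps,
# global image SNR, Sobel mean-gradient difficulty, and Pearson
# correlation.

check_same_shape <- function(a, b) {
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b))) {
    stop("maps must be matrices of identical shape", call. = FALSE)
  }
  invisible(NULL)
}

#' Dice similarity coefficient
#'
#' DSC = 2 TP / (2 TP + FP + FN), where the positive class is an edge
#' pixel. Symmetric in its arguments; defined as 1 when both maps are
#' empty (perfect agreement) and 0 when exactly one is empty.
#'
#' @param predicted,truth Binary matrices (0/1) of identical shape.
#' @return Value in \[0, 1\].
#' @export
dsc <- function(predicted, truth) {
  check_same_shape(predicted, truth)
  check_binary_map(predicted); check_binary_map(truth)
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  denom <- 2 * tp + fp + fn
  if (denom == 0) 1 else 2 * tp / denom
}

#' Peak signal-to-noise ratio of binary edge maps
#'
#' Maps are compared on the \{0, 255\} scale: PSNR = 10 log10(255^2 / MSE)
#' in dB, +Inf for identical maps.
#'
#' @param predicted,truth Binary matrices (0/1) of identical shape.
#' @return PSNR in dB (possibly \code{Inf}).
#' @export
psnr <- function(predicted, truth) {
  check_same_shape(predicted, truth)
  mse <- mean((255 * (predicted - truth))^2)
  if (mse == 0) Inf else 10 * log10(255^2 / mse)
}

#' Structural similarity of binary edge maps
#'
#' Mean local SSIM index computed on the \{0, 255\} scale with an 11x11
#' Gaussian window (sigma = 1.5), K1 = 0.01, K2 = 0.03, data range 255,
#' population (weighted) variances, and symmetric boundary padding. The
#' 5-pixel border, where window support is incomplete, is excluded from
#' the mean.
#'
#' @param predicted,truth Binary matrices (0/1), at least 11x11.
#' @return Value in \[-1, 1\].
#' @export
ssim <- function(predicted, truth) {
  check_same_shape(predicted, truth)
  if (nrow(predicted) < 11L || ncol(predicted) < 11L) {
    stop("maps must be at least 11x11 for SSIM", call. = FALSE)
  }
  x <- predicted * 255; y <- truth * 255
  k <- local({
    g <- exp(-((-5:5)^2) / (2 * 1.5^2)); g / sum(g)
  })
  f <- function(m) convolve_separable(m, k)
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  mx <- f(x); my <- f(y)
  vx <- f(x * x) - mx^2
  vy <- f(y * y) - my^2
  cxy <- f(x * y) - mx * my
  smap <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
          ((mx^2 + my^2 + c1) * (vx + vy + c2))
  core <- smap[6:(nrow(smap) - 5L), 6:(ncol(smap) - 5L)]
  mean(core)
}

#' Global image signal-to-noise ratio
#'
#' Mean intensity divided by the (sample) standard deviation of
#' intensity over the whole image.
#'
#' @param image Numeric matrix with non-zero intensity spread.
#' @return SNR (dimensionless).
#' @export
snr_image <- function(image) {
  check_image(image, min_dim = 1L)
  s <- stats::sd(image)
  if (s == 0) stop("SNR undefined for a constant image", call. = FALSE)
  mean(image) / s
}

#' Mean Sobel gradient (edge-detection difficulty)
#'
#' Mean over all pixels of sqrt(Gx^2 + Gy^2) with the standard 3x3 Sobel
#' kernels and reflective boundary handling. Higher values indicate more
#' local contrast and, for noisy images, a harder edge-detection problem.
#'
#' @param image Numeric matrix, at least 3x3.
#' @return Non-negative scalar.
#' @export
mean_gradient_difficulty <- function(image) {
  check_image(image)
  mean(sobel_gradients(image)$magnitude)
}

#' Pearson correlation
#'
#' Sample Pearson correlation between two equal-length, non-constant
#' sequences.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("'x' and 'y' must have equal length >= 2", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant sequence", call. = FALSE)
  }
  stats::cor(x, y)
}
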
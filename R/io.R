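# File interfaces: 8-bit grayscale PNG/TIFF images, edge maps as
# {0, 255} PNGs, detector parameters as YAML or JSON.

#' Read a grayscale image
#'
#' Reads an 8-bit grayscale PNG or TIFF (by extension) into a numeric
#' matrix on the 0..255 scale. Color inputs are converted by channel
#' averaging.
#'
#' @param path File path ending in \code{.png}, \code{.tif} or
#'   \code{.tiff}.
#' @return Numeric matrix of intensities in \[0, 255\].
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(raw)) == 3L) raw <- apply(raw[, , 1:min(3L, dim(raw)[3L])], c(1, 2), mean)
  raw * 255
}

#' Write a grayscale image
#'
#' Writes a numeric matrix (0..255 scale, clipped) as an 8-bit grayscale
#' PNG or TIFF.
#'
#' @param image Numeric matrix.
#' @param path Output path ending in \code{.png}, \code{.tif} or
#'   \code{.tiff}.
#' @export
write_gray_image <- function(image, path) {
  norm <- pmin(pmax(image, 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(norm, path),
         tif = ,
         tiff = tiff::writeTIFF(norm, path, bits.per.sample = 8L),
         stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' Write an edge map
#'
#' Serializes a binary edge map as a PNG with values \{0, 255\}.
#'
#' @param edges Binary matrix (0/1).
#' @param path Output path ending in \code{.png}.
#' @export
write_edge_map <- function(edges, path) {
  check_binary_map(edges)
  write_gray_image(edges * 255, path)
}

#' Read an edge map
#'
#' Reads a \{0, 255\} PNG back into a binary 0/1 matrix (threshold at
#' half scale).
#'
#' @param path PNG path.
#' @return Binary matrix (0/1).
#' @export
read_edge_map <- function(path) {
  img <- read_gray_image(path)
  matrix(as.numeric(img > 127.5), nrow(img), ncol(img))
}

#' Save detector parameters
#'
#' Writes the triplet as YAML or JSON (by extension):
#' \code{{delta: int, tau: float, rule: int}}.
#'
#' @param params A [detector_params()] object.
#' @param path Output path ending in \code{.yaml}, \code{.yml} or
#'   \code{.json}.
#' @export
write_detector_params <- function(params, path) {
  stopifnot(inherits(params, "detector_params"))
  x <- list(delta = params$delta, tau = params$tau, rule = params$rule)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         yaml = ,
         yml = yaml::write_yaml(x, path),
         json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
         stop("unsupported parameter format: .", ext, call. = FALSE))
  invisible(path)
}

#' Load detector parameters
#'
#' @param path YAML or JSON path written by [write_detector_params()].
#' @return A [detector_params()] object.
#' @export
read_detector_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              yaml = ,
              yml = yaml::read_yaml(path),
              json = jsonlite::read_json(path),
              stop("unsupported parameter format: .", ext, call. = FALSE))
  detector_params(delta = x$delta, tau = x$tau, rule = x$rule)
}

#' Write an optimization history as CSV
#'
#' One row per (unit, epoch) with the global-best fitness and the
#' denormalized triplet, as produced by [optimize_dataset()] or found in
#' a \code{"caed"} fit.
#'
#' @param history Data frame with columns unit, epoch, gbest_fitness,
#'   delta, tau, rule.
#' @param path Output CSV path.
#' @export
write_history_csv <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
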
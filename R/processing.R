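# Pre- and post-processing around the CA detector, the three scenario
# pipelines, and the Canny baseline used for comparison.

#' Scenario configuration
#'
#' Describes one of the three detection pipelines: \code{"plain"} applies
#' the CA rule alone; \code{"post"} adds thinning and disconnected-edge
#' removal; \code{"pre_post"} additionally Gaussian-smooths the input
#' first.
#'
#' @param scenario One of \code{"plain"}, \code{"post"}, \code{"pre_post"}.
#' @param sigma_smooth Standard deviation (pixels) of the Gaussian
#'   pre-filter; 0 disables smoothing. Only used by \code{"pre_post"}.
#' @param min_component_size Connected components (8-connectivity) smaller
#'   than this are removed in post-processing.
#' @param fitness_post If \code{TRUE}, optimization fitness is evaluated on
#'   the fully post-processed map instead of the plain CA output.
#' @return A list of class \code{"scenario_config"}.
#' @export
scenario_config <- function(scenario = c("plain", "post", "pre_post"),
                            sigma_smooth = 1.5, min_component_size = 8L,
                            fitness_post = FALSE) {
  scenario <- match.arg(scenario)
  if (sigma_smooth < 0) stop("'sigma_smooth' must be non-negative", call. = FALSE)
  if (min_component_size < 1) stop("'min_component_size' must be >= 1", call. = FALSE)
  structure(list(scenario = scenario,
                 sigma_smooth = if (scenario == "pre_post") sigma_smooth else 0,
                 min_component_size = as.integer(min_component_size),
                 fitness_post = isTRUE(fitness_post)),
            class = "scenario_config")
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3.5 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with symmetric (reflective) padding.
convolve_separable <- function(image, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  reflect_idx <- function(n) c(pmin(r:1, n), seq_len(n), pmax(n - seq_len(r) + 1L, 1L))
  pad <- image[reflect_idx(nrow(image)), , drop = FALSE]
  out <- matrix(0, nrow(image), ncol(image))
  for (t in seq_along(kernel)) {
    out <- out + kernel[t] * pad[seq_len(nrow(image)) + t - 1L, , drop = FALSE]
  }
  pad <- out[, reflect_idx(ncol(image)), drop = FALSE]
  out[] <- 0
  for (t in seq_along(kernel)) {
    out <- out + kernel[t] * pad[, seq_len(ncol(image)) + t - 1L, drop = FALSE]
  }
  out
}

#' Gaussian pre-filter
#'
#' Smooths an image with a normalized, separable Gaussian kernel
#' (truncated at 3.5 sigma) using reflective boundary handling, which
#' preserves the image mean. \code{sigma_smooth = 0} returns the input
#' unchanged.
#'
#' @param image Numeric matrix.
#' @param sigma_smooth Non-negative standard deviation in pixels.
#' @return Smoothed matrix, same dimensions (real-valued; no
#'   re-quantization).
#' @export
gaussian_prefilter <- function(image, sigma_smooth) {
  check_image(image, min_dim = 1L)
  if (length(sigma_smooth) != 1L || is.na(sigma_smooth) || sigma_smooth < 0) {
    stop("'sigma_smooth' must be a single non-negative number", call. = FALSE)
  }
  if (sigma_smooth == 0) return(image)
  convolve_separable(image, gaussian_kernel_1d(sigma_smooth))
}

# Count of 8-neighbors that are edge pixels (outside the frame counts 0).
neighbor_count <- function(map) {
  h <- nrow(map); w <- ncol(map)
  padded <- matrix(0, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- map
  acc <- matrix(0, h, w)
  for (m in seq_len(9L)) {
    dr <- moore_offsets[m, 1L]; dc <- moore_offsets[m, 2L]
    if (dr == 0L && dc == 0L) next
    acc <- acc + padded[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
  }
  acc
}

#' Thin edges to one-pixel-wide curves
#'
#' Zhang–Suen morphological thinning: alternating sub-iterations delete
#' boundary pixels that have 2..6 edge neighbors, a single 0-to-1
#' transition around the neighborhood, and satisfy the sub-iteration's
#' directional conditions, until no pixel changes. The output edge set is
#' a subset of the input and the operation is idempotent.
#'
#' @param edges Binary matrix (0/1).
#' @return Thinned binary matrix of the same dimensions.
#' @export
thin_edges <- function(edges) {
  check_binary_map(edges)
  h <- nrow(edges); w <- ncol(edges)
  if (h < 3L || w < 3L) return(edges)
  p <- matrix(0, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- edges
  core_r <- 2:(h + 1L); core_c <- 2:(w + 1L)
  # clockwise neighbor order starting north: P2..P9
  nb_off <- list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                 c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- lapply(nb_off, function(o) p[core_r + o[1L], core_c + o[2L]])
      B <- Reduce(`+`, nb)
      A <- matrix(0, h, w)
      for (m in 1:8) {
        nxt <- nb[[if (m == 8L) 1L else m + 1L]]
        A <- A + (nb[[m]] == 0) * (nxt == 1)
      }
      if (step == 1L) {
        cond <- nb[[1L]] * nb[[3L]] * nb[[5L]] == 0 &
                nb[[3L]] * nb[[5L]] * nb[[7L]] == 0
      } else {
        cond <- nb[[1L]] * nb[[3L]] * nb[[7L]] == 0 &
                nb[[1L]] * nb[[5L]] * nb[[7L]] == 0
      }
      del <- p[core_r, core_c] == 1 & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        sub <- p[core_r, core_c]
        sub[del] <- 0
        p[core_r, core_c] <- sub
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p[core_r, core_c]
}

# 8-connected component labeling by iterative flood fill over linear
# indices of foreground pixels; returns an integer matrix of labels
# (0 = background).
label_components <- function(map) {
  h <- nrow(map); w <- ncol(map)
  labels <- matrix(0L, h, w)
  fg <- which(map == 1)
  if (length(fg) == 0L) return(labels)
  current <- 0L
  stack <- integer(length(fg))
  for (start in fg) {
    if (labels[start] != 0L) next
    current <- current + 1L
    top <- 1L
    stack[1L] <- start
    labels[start] <- current
    while (top > 0L) {
      px <- stack[top]
      top <- top - 1L
      r0 <- ((px - 1L) %% h) + 1L
      c0 <- ((px - 1L) %/% h) + 1L
      rr <- max(1L, r0 - 1L):min(h, r0 + 1L)
      cc <- max(1L, c0 - 1L):min(w, c0 + 1L)
      for (cn in cc) for (rn in rr) {
        idx <- (cn - 1L) * h + rn
        if (map[idx] == 1 && labels[idx] == 0L) {
          labels[idx] <- current
          top <- top + 1L
          stack[top] <- idx
        }
      }
    }
  }
  labels
}

#' Remove small disconnected edge components
#'
#' Deletes 8-connected components of edge pixels whose size is below
#' \code{min_component_size}; larger components are untouched.
#'
#' @param edges Binary matrix (0/1).
#' @param min_component_size Positive integer; 1 is the identity.
#' @return Binary matrix of the same dimensions.
#' @export
remove_disconnected <- function(edges, min_component_size = 8L) {
  check_binary_map(edges)
  if (min_component_size < 1) stop("'min_component_size' must be >= 1", call. = FALSE)
  if (min_component_size == 1L) return(edges)
  labels <- label_components(edges)
  if (max(labels) == 0L) return(edges)
  sizes <- tabulate(labels)
  keep <- which(sizes >= min_component_size)
  out <- matrix(as.numeric(labels %in% keep), nrow(edges), ncol(edges))
  out
}

#' Run a detection scenario
#'
#' Applies one of the three pipelines: \code{plain} is the bare CA
#' detector; \code{post} follows it with thinning and disconnected-edge
#' removal; \code{pre_post} Gaussian-smooths the input first and then runs
#' the post path.
#'
#' @param image Numeric matrix.
#' @param params A [detector_params()] object.
#' @param cfg A [scenario_config()] object.
#' @return Binary edge map.
#' @export
run_scenario <- function(image, params, cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (cfg$scenario == "pre_post" && cfg$sigma_smooth > 0) {
    image <- gaussian_prefilter(image, cfg$sigma_smooth)
  }
  edges <- apply_detector(image, params)
  if (cfg$scenario %in% c("post", "pre_post")) {
    edges <- remove_disconnected(thin_edges(edges), cfg$min_component_size)
  }
  edges
}

sobel_gradients <- function(image) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  # 2-D convolution with symmetric padding via the separable decomposition
  # Sobel = smoothing [1 2 1] x derivative [-1 0 1]
  smooth <- c(1, 2, 1); deriv <- c(-1, 0, 1)
  conv1d <- function(m, k, along_rows) {
    r <- 1L
    reflect_idx <- function(n) c(1L, seq_len(n), n)
    if (along_rows) {
      pad <- m[reflect_idx(nrow(m)), , drop = FALSE]
      out <- matrix(0, nrow(m), ncol(m))
      for (t in 1:3) out <- out + k[t] * pad[seq_len(nrow(m)) + t - 1L, , drop = FALSE]
    } else {
      pad <- m[, reflect_idx(ncol(m)), drop = FALSE]
      out <- matrix(0, nrow(m), ncol(m))
      for (t in 1:3) out <- out + k[t] * pad[, seq_len(ncol(m)) + t - 1L, drop = FALSE]
    }
    out
  }
  gx <- conv1d(conv1d(image, deriv, FALSE), smooth, TRUE)   # horizontal change
  gy <- conv1d(conv1d(image, deriv, TRUE), smooth, FALSE)   # vertical change
  list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2))
}

#' Canny baseline edge detector
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and double thresholding with hysteresis:
#' weak edges (magnitude above the low threshold) survive only when
#' 8-connected to a strong edge (magnitude above the high threshold).
#' Default thresholds are 10% and 20% of the 8-bit maximum (25.5 and 51).
#'
#' @param image Numeric matrix in the 0..255 range.
#' @param sigma Gaussian smoothing standard deviation; 0 skips smoothing.
#' @param low,high Absolute gradient-magnitude thresholds.
#' @return Binary edge map.
#' @export
canny_baseline <- function(image, sigma = 1.5, low = 25.5, high = 51) {
  check_image(image)
  smoothed <- gaussian_prefilter(image, sigma)
  g <- sobel_gradients(smoothed)
  mag <- g$magnitude
  h <- nrow(mag); w <- ncol(mag)
  # quantize gradient direction into 4 sectors and suppress non-maxima
  ang <- atan2(g$gy, g$gx) %% pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  off <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  keep <- matrix(FALSE, h, w)
  padded <- matrix(0, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- mag
  core_r <- 2:(h + 1L); core_c <- 2:(w + 1L)
  for (s in 0:3) {
    d <- off[[s + 1L]]
    n1 <- padded[core_r + d[1L], core_c + d[2L]]
    n2 <- padded[core_r - d[1L], core_c - d[2L]]
    keep <- keep | (sector == s & mag >= n1 & mag >= n2)
  }
  weak <- keep & mag >= low
  strong <- keep & mag >= high
  if (!any(strong)) return(matrix(0, h, w))
  labels <- label_components(matrix(as.numeric(weak), h, w))
  good <- unique(labels[strong])
  matrix(as.numeric(labels %in% good[good > 0L]), h, w)
}
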
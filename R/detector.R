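# The two-step cellular-automaton transition rule: a linear rule selects
# which Moore neighbors enter the absolute-difference sum phi, the
# membership ratio mu = phi / (delta + phi) saturates local contrast into
# [0,1], and thresholding at tau gives the binary edge state. One
# synchronous pass over the lattice produces the edge map.

#' Detector parameter triplet
#'
#' Bundles the three tunable parameters of the cellular-automaton edge
#' detector: the damping constant \code{delta} (larger values suppress
#' edges), the membership threshold \code{tau}, and the 9-bit linear
#' \code{rule} selecting the contributing Moore neighbors.
#'
#' @param delta Integer in 0..255.
#' @param tau Real in \[0, 1).
#' @param rule Integer in 0..511.
#' @return An object of class \code{"detector_params"}: a list with
#'   elements \code{delta}, \code{tau}, \code{rule}.
#' @examples
#' detector_params(delta = 100, tau = 0.3, rule = 495)
#' @export
detector_params <- function(delta, tau, rule) {
  if (length(delta) != 1L || is.na(delta) || delta != as.integer(delta) ||
      delta < 0 || delta > 255) {
    stop("'delta' must be a single integer in 0..255", call. = FALSE)
  }
  if (length(tau) != 1L || is.na(tau) || tau < 0 || tau >= 1) {
    stop("'tau' must be a single real in [0, 1)", call. = FALSE)
  }
  rule_to_bits(rule)  # range check
  structure(list(delta = as.integer(delta), tau = as.numeric(tau),
                 rule = as.integer(rule)),
            class = "detector_params")
}

#' @export
print.detector_params <- function(x, ...) {
  cat(sprintf("CA edge-detector parameters: delta = %d, tau = %.4f, rule = %d (%d neighbors)\n",
              x$delta, x$tau, x$rule, sum(rule_to_bits(x$rule))))
  invisible(x)
}

check_image <- function(image, min_dim = 3L) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (nrow(image) < min_dim || ncol(image) < min_dim) {
    stop(sprintf("image must be at least %dx%d", min_dim, min_dim),
         call. = FALSE)
  }
  invisible(image)
}

check_binary_map <- function(map) {
  if (!is.matrix(map) || !all(map %in% c(0, 1))) {
    stop("edge map must be a matrix with values in {0, 1}", call. = FALSE)
  }
  invisible(map)
}

# Shift a matrix by (dr, dc) with edge-replicate padding: entry (i, j) of
# the result is m[clamp(i + dr), clamp(j + dc)].
shift_replicate <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  m[pmin(pmax(seq_len(h) + dr, 1L), h),
    pmin(pmax(seq_len(w) + dc, 1L), w), drop = FALSE]
}

# Precompute the nine |X(i,j) - X(i+dr, j+dc)| layers (replicate padding)
# as a (h*w) x 9 matrix; column m corresponds to moore_offsets[m, ].
# Every per-pixel quantity of the detector is a subset-sum of these
# columns, which lets rule sweeps and swarm evaluations run as a single
# matrix product.
neighbor_absdiff <- function(image) {
  check_image(image)
  out <- matrix(0, nrow = length(image), ncol = 9L)
  for (m in seq_len(9L)) {
    out[, m] <- abs(image - shift_replicate(image, moore_offsets[m, 1L],
                                            moore_offsets[m, 2L]))
  }
  out
}

#' Local absolute-difference sum
#'
#' phi(i, j) = sum over the selected offsets (k, l) of
#' |X(i, j) - X(i + k, j + l)|. Out-of-bounds neighbors take the nearest
#' in-bounds value (edge-replicate padding), so border pixels see zero
#' difference toward the outside. The center offset (0, 0) contributes 0.
#'
#' @param image Numeric matrix of intensities.
#' @param i,j Row and column of the pixel (1-based).
#' @param mask Neighbor mask as returned by [decode_rule()].
#' @return Non-negative scalar.
#' @export
difference_sum <- function(image, i, j, mask) {
  check_image(image, min_dim = 1L)
  h <- nrow(image); w <- ncol(image)
  if (i < 1 || i > h || j < 1 || j > w) stop("(i, j) outside the image", call. = FALSE)
  mask <- as.matrix(mask)
  if (nrow(mask) == 0L) return(0)
  ni <- pmin(pmax(i + mask[, 1L], 1L), h)
  nj <- pmin(pmax(j + mask[, 2L], 1L), w)
  sum(abs(image[i, j] - image[cbind(ni, nj)]))
}

#' Edge-membership ratio
#'
#' mu = phi / (delta + phi), the saturating map from the local
#' absolute-difference sum to \[0, 1\]. The degenerate case delta = 0,
#' phi = 0 is defined as 0: a flat neighborhood is not an edge.
#'
#' @param phi Non-negative difference sum (vectorized).
#' @param delta Damping constant, integer in 0..255.
#' @return Value(s) in \[0, 1\], strictly increasing in \code{phi} for
#'   \code{delta} > 0.
#' @export
edge_membership <- function(phi, delta) {
  if (any(phi < 0)) stop("'phi' must be non-negative", call. = FALSE)
  denom <- delta + phi
  ifelse(denom > 0, phi / denom, 0)
}

#' Threshold an edge-membership value
#'
#' Returns 1 iff mu > tau; membership exactly equal to tau maps to 0.
#'
#' @param mu Membership value(s) in \[0, 1\].
#' @param tau Threshold in \[0, 1).
#' @return 0/1 value(s).
#' @export
threshold_membership <- function(mu, tau) {
  if (length(tau) != 1L || is.na(tau) || tau < 0 || tau >= 1) {
    stop("'tau' must be a single real in [0, 1)", call. = FALSE)
  }
  as.numeric(mu > tau)
}

#' Apply the cellular-automaton edge detector
#'
#' One synchronous pass of the two-step transition rule: for every pixel,
#' the linear rule's neighbors enter the absolute-difference sum, the
#' membership ratio is formed with \code{delta}, and the result is
#' thresholded at \code{tau}. The output is a binary edge map of the same
#' shape as the input.
#'
#' @param image Numeric matrix, at least 3x3.
#' @param params A [detector_params()] object.
#' @return Binary matrix (0/1) of the same dimensions.
#' @examples
#' img <- matrix(0, 5, 5); img[, 3:5] <- 255
#' apply_detector(img, detector_params(255, 0.4, 495))
#' @export
apply_detector <- function(image, params) {
  check_image(image)
  stopifnot(inherits(params, "detector_params"))
  bits <- rule_to_bits(params$rule)
  if (!any(bits)) return(matrix(0, nrow(image), ncol(image)))
  layers <- neighbor_absdiff(image)
  phi <- rowSums(layers[, bits, drop = FALSE])
  mu <- edge_membership(phi, params$delta)
  matrix(threshold_membership(mu, params$tau), nrow(image), ncol(image))
}
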
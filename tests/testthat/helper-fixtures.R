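# Shared fixtures and independent oracles, all built in code.

# Naive per-pixel reference detector: explicit double loop over pixels
# and neighbor offsets with replicate padding. Kept deliberately
# independent of the vectorized implementation.
reference_detector <- function(image, delta, tau, rule) {
  h <- nrow(image); w <- ncol(image)
  bits <- as.logical(bitwAnd(as.integer(rule), 2L^(0:8)))
  offsets <- cbind(rep(-1:1, each = 3), rep(-1:1, times = 3))[bits, , drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    phi <- 0
    if (nrow(offsets) > 0) for (m in seq_len(nrow(offsets))) {
      ni <- min(max(i + offsets[m, 1], 1), h)
      nj <- min(max(j + offsets[m, 2], 1), w)
      phi <- phi + abs(image[i, j] - image[ni, nj])
    }
    mu <- if (delta + phi > 0) phi / (delta + phi) else 0
    out[i, j] <- as.numeric(mu > tau)
  }
  out
}

# Per-pixel confusion-count oracle for the Dice coefficient.
reference_dsc <- function(pred, truth) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1
  }
  if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
}

random_params <- function() {
  detector_params(delta = sample(0:255, 1),
                  tau = stats::runif(1, 0, 0.999),
                  rule = sample(0:511, 1))
}

# vertical step image with optional noise
step_image <- function(h, w, low = 0, high = 255, split = w %/% 2) {
  img <- matrix(low, h, w)
  img[, (split + 1):w] <- high
  img
}

# sharp-boundary disk on a dark background
disk_image <- function(n = 64, radius = 20, fg = 200, bg = 10) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  d <- sqrt((cols - (n + 1) / 2)^2 + (rows - (n + 1) / 2)^2)
  img <- matrix(bg, n, n)
  img[d <= radius] <- fg
  img
}

# deterministic binary 32x32 pair used for the frozen SSIM cross-check
deterministic_pair <- function() {
  i <- matrix(rep(1:32, times = 32), 32)
  j <- matrix(rep(1:32, each = 32), 32)
  list(p = matrix(as.numeric(((i * 7 + j * 3) %% 5) == 0), 32),
       t = matrix(as.numeric(((i * 2 + j * 5) %% 7) < 2), 32))
}

# small phantoms for optimizer tests
small_phantoms <- function(n, class = "low", master_seed = 100, size = 64) {
  make_optimization_set(n, class, master_seed = master_seed, size = size,
                        radius_range = c(10, 20), center_jitter = 3)
}

count_edge_neighbors <- function(map) {
  h <- nrow(map); w <- ncol(map)
  p <- matrix(0, h + 2, w + 2)
  p[2:(h + 1), 2:(w + 1)] <- map
  acc <- matrix(0, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc + p[(2:(h + 1)) + dr, (2:(w + 1)) + dc]
  }
  acc
}
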
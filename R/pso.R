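# Particle swarm optimization of the detector triplet (delta, tau, rule)
# in its normalized continuous form (delta/255, tau, rule/511) against
# ground-truth edge maps, with Dice-coefficient fitness. Supports the
# per-image protocol (batch size 1) and batched optimization with fitness
# averaging; the global best (and, for comparability, each particle's
# personal best) is reset between consecutive batches.

#' Swarm configuration
#'
#' Particle swarm hyperparameters. The defaults are a 100-particle swarm
#' run for 25 epochs per optimization unit with inertia 0.05, personal
#' (history) factor 2.1 and social (swarm-influence) factor 1.2.
#'
#' @param n_particles Number of particles.
#' @param epochs_per_unit Velocity/position update cycles per unit
#'   (image or batch).
#' @param omega Inertia weight.
#' @param c1,c2 Personal-best and global-best attraction factors.
#' @param v_max Per-component velocity clamp.
#' @param seed Optional integer seed; fixes the whole optimization
#'   trajectory.
#' @return A list of class \code{"swarm_config"}.
#' @export
swarm_config <- function(n_particles = 100L, epochs_per_unit = 25L,
                         omega = 0.05, c1 = 2.1, c2 = 1.2,
                         v_max = 1.0, seed = NULL) {
  stopifnot(n_particles >= 1, epochs_per_unit >= 1,
            omega >= 0, c1 >= 0, c2 >= 0, v_max > 0)
  structure(list(n_particles = as.integer(n_particles),
                 epochs_per_unit = as.integer(epochs_per_unit),
                 omega = omega, c1 = c1, c2 = c2, v_max = v_max,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "swarm_config")
}

#' Normalize detector parameters to the unit cube
#'
#' Maps (delta, tau, rule) to its continuous search representation
#' (delta/255, tau, rule/511).
#'
#' @param params A [detector_params()] object.
#' @return Named numeric vector \code{c(delta_n, tau, rule_n)}.
#' @export
normalize_params <- function(params) {
  stopifnot(inherits(params, "detector_params"))
  c(delta_n = params$delta / 255, tau = params$tau, rule_n = params$rule / 511)
}

#' Denormalize a unit-cube position to detector parameters
#'
#' Inverse of [normalize_params()]: components are clamped to \[0, 1\]
#' (tau to \[0, 1)), then delta and rule are recovered by round-half-up
#' scaling.
#'
#' @param np Numeric 3-vector (delta_n, tau, rule_n).
#' @return A [detector_params()] object.
#' @export
denormalize_params <- function(np) {
  np <- pmin(pmax(as.numeric(np), 0), 1)
  detector_params(delta = floor(np[1L] * 255 + 0.5),
                  tau = min(np[2L], 1 - 1e-9),
                  rule = floor(np[3L] * 511 + 0.5))
}

#' Update a particle's velocity
#'
#' v(t+1) = omega v(t) + r1 c1 (pbest - x) + r2 c2 (gbest - x), with r1 and
#' r2 drawn independently per dimension from U(0, 1), then clamped
#' componentwise to \[-v_max, v_max\].
#'
#' @param velocity,position,pbest,gbest Numeric 3-vectors.
#' @param config A [swarm_config()] object.
#' @param r1,r2 Optional fixed random factors (3-vectors), for testing;
#'   drawn from the current RNG stream when \code{NULL}.
#' @return New velocity 3-vector.
#' @export
update_velocity <- function(velocity, position, pbest, gbest, config,
                            r1 = NULL, r2 = NULL) {
  if (is.null(r1)) r1 <- stats::runif(length(velocity))
  if (is.null(r2)) r2 <- stats::runif(length(velocity))
  v <- config$omega * velocity +
    r1 * config$c1 * (pbest - position) +
    r2 * config$c2 * (gbest - position)
  pmin(pmax(v, -config$v_max), config$v_max)
}

#' Update a particle's position
#'
#' x(t+1) = x(t) + v(t+1), clamped componentwise to \[0, 1\].
#'
#' @param position,velocity Numeric 3-vectors.
#' @return New position 3-vector.
#' @export
update_position <- function(position, velocity) {
  pmin(pmax(position + velocity, 0), 1)
}

#' Construct a labeled sample
#'
#' @param image Numeric intensity matrix.
#' @param truth Binary ground-truth edge map of the same shape.
#' @return A list of class \code{"labeled_sample"}.
#' @export
labeled_sample <- function(image, truth) {
  check_image(image)
  check_binary_map(truth)
  if (!all(dim(image) == dim(truth))) {
    stop("image and truth must have identical shape", call. = FALSE)
  }
  structure(list(image = image, truth = truth), class = "labeled_sample")
}

# Precompute, per sample, the pre-filtered image's absolute-difference
# layers and the truth vector. All swarm fitness evaluations on the batch
# reduce to matrix products against these layers.
prepare_batch <- function(batch, scenario) {
  lapply(batch, function(s) {
    stopifnot(inherits(s, "labeled_sample"))
    img <- if (scenario$scenario == "pre_post" && scenario$sigma_smooth > 0) {
      gaussian_prefilter(s$image, scenario$sigma_smooth)
    } else s$image
    list(layers = neighbor_absdiff(img), truth = as.numeric(s$truth),
         dim = dim(s$image), image = img, truth_map = s$truth)
  })
}

# Fitness of all particle positions (n x 3 matrix) on a prepared batch:
# mean DSC over the batch, evaluated at the denormalized integer triplet.
swarm_fitness <- function(positions, prepared, scenario) {
  n <- nrow(positions)
  delta <- floor(pmin(pmax(positions[, 1L], 0), 1) * 255 + 0.5)
  tau <- pmin(pmax(positions[, 2L], 0), 1 - 1e-9)
  rule <- floor(pmin(pmax(positions[, 3L], 0), 1) * 511 + 0.5)
  bits <- matrix(0, 9L, n)
  for (b in 0:8) bits[b + 1L, ] <- bitwAnd(as.integer(rule), bitwShiftL(1L, b)) > 0
  total <- numeric(n)
  for (s in prepared) {
    if (scenario$fitness_post) {
      d <- numeric(n)
      for (k in seq_len(n)) {
        p <- detector_params(delta[k], tau[k], rule[k])
        pred <- apply_detector(s$image, p)
        pred <- remove_disconnected(thin_edges(pred), scenario$min_component_size)
        d[k] <- dsc(pred, s$truth_map)
      }
      total <- total + d
      next
    }
    phi <- s$layers %*% bits                      # pixels x particles
    mu <- phi / (phi + rep(delta, each = nrow(phi)))
    mu[is.nan(mu)] <- 0                           # delta = 0, phi = 0
    pred <- mu > rep(tau, each = nrow(mu))
    tpos <- s$truth == 1
    tp <- colSums(pred & tpos)
    fp <- colSums(pred & !tpos)
    fn <- sum(tpos) - tp
    denom <- 2 * tp + fp + fn
    total <- total + ifelse(denom == 0, 1, 2 * tp / denom)
  }
  total / length(prepared)
}

#' Evaluate the Dice fitness of a candidate solution
#'
#' Runs the scenario's detector path on every sample of the batch and
#' returns the arithmetic mean of the per-sample Dice coefficients
#' against the ground truth. By default the plain CA edge map (on the
#' scenario's pre-filtered image) is scored; set
#' \code{fitness_post = TRUE} in the scenario to score the post-processed
#' map instead.
#'
#' @param np Normalized position (3-vector) or a [detector_params()]
#'   object.
#' @param batch Non-empty list of [labeled_sample()] objects.
#' @param scenario A [scenario_config()] object.
#' @return Mean DSC in \[0, 1\].
#' @export
evaluate_fitness <- function(np, batch, scenario = scenario_config("plain")) {
  if (length(batch) == 0L) stop("batch must be non-empty", call. = FALSE)
  if (inherits(np, "detector_params")) np <- normalize_params(np)
  prepared <- prepare_batch(batch, scenario)
  swarm_fitness(matrix(np, nrow = 1L), prepared, scenario)[1L]
}

init_swarm <- function(config) {
  n <- config$n_particles
  list(positions = matrix(stats::runif(3L * n), n, 3L),
       velocities = matrix(stats::runif(3L * n, -0.1, 0.1), n, 3L))
}

#' Optimize the detector on one unit (image or batch)
#'
#' Runs \code{epochs_per_unit} synchronous PSO iterations of the whole
#' swarm on a fixed batch. Personal bests update on strict fitness
#' improvement; the global best is the best personal best. When an
#' existing swarm is passed in (continuation from a previous unit),
#' positions and velocities carry over while personal and global bests
#' are reset and re-evaluated on the new batch, so that fitness values
#' remain comparable within the unit.
#'
#' @param batch Non-empty list of [labeled_sample()] objects.
#' @param config A [swarm_config()] object.
#' @param scenario A [scenario_config()] object used for fitness.
#' @param swarm Optional swarm state from a previous unit.
#' @return A list with \code{best} (normalized 3-vector), \code{fitness},
#'   \code{swarm} (state for continuation), and \code{history} (data
#'   frame of the global-best fitness per epoch).
#' @export
optimize_unit <- function(batch, config = swarm_config(),
                          scenario = scenario_config("plain"),
                          swarm = NULL) {
  if (length(batch) == 0L) stop("batch must be non-empty", call. = FALSE)
  prepared <- prepare_batch(batch, scenario)
  if (is.null(swarm)) swarm <- init_swarm(config)
  pos <- swarm$positions; vel <- swarm$velocities
  n <- nrow(pos)
  # (re-)evaluate at current positions: pbest reset on unit entry
  fit <- swarm_fitness(pos, prepared, scenario)
  pbest <- pos; pbest_fit <- fit
  g <- which.max(pbest_fit)
  gbest <- pbest[g, ]; gbest_fit <- pbest_fit[g]
  snapshot <- function(epoch) {
    p <- denormalize_params(gbest)
    data.frame(epoch = epoch, gbest_fitness = gbest_fit,
               delta = p$delta, tau = p$tau, rule = p$rule)
  }
  history <- snapshot(0L)
  for (epoch in seq_len(config$epochs_per_unit)) {
    r1 <- matrix(stats::runif(3L * n), n, 3L)
    r2 <- matrix(stats::runif(3L * n), n, 3L)
    vel <- config$omega * vel +
      r1 * config$c1 * (pbest - pos) +
      r2 * config$c2 * (matrix(gbest, n, 3L, byrow = TRUE) - pos)
    vel <- pmin(pmax(vel, -config$v_max), config$v_max)
    pos <- pmin(pmax(pos + vel, 0), 1)
    fit <- swarm_fitness(pos, prepared, scenario)
    improved <- fit > pbest_fit
    pbest[improved, ] <- pos[improved, ]
    pbest_fit[improved] <- fit[improved]
    g <- which.max(pbest_fit)
    if (pbest_fit[g] > gbest_fit) {
      gbest <- pbest[g, ]; gbest_fit <- pbest_fit[g]
    }
    history <- rbind(history, snapshot(epoch))
  }
  list(best = gbest, fitness = gbest_fit,
       swarm = list(positions = pos, velocities = vel),
       history = history)
}

#' Optimize the detector over a dataset of labeled samples
#'
#' Partitions the samples into consecutive batches of \code{batch_size}
#' (the last may be shorter) and optimizes each batch for
#' \code{epochs_per_unit} epochs. Between batches the global best is
#' reset — particles keep their positions and velocities but personal
#' bests are re-seeded from the current positions on the new batch — to
#' avoid the swarm getting stuck in optima of earlier units.
#' \code{batch_size = 1} is the per-image protocol. The returned
#' parameters are the global best of the final unit; the full history is
#' retained for other consolidation choices.
#'
#' @param samples Non-empty list of [labeled_sample()] objects.
#' @param batch_size Positive integer.
#' @param config A [swarm_config()] object; \code{config$seed}, when set,
#'   makes the trajectory fully reproducible.
#' @param scenario A [scenario_config()] object used for fitness.
#' @return A list with \code{params} ([detector_params()]),
#'   \code{normalized}, \code{fitness} (final-unit gbest DSC), and
#'   \code{history} (data frame with unit, epoch, gbest fitness and the
#'   denormalized triplet).
#' @export
optimize_dataset <- function(samples, batch_size = 1L,
                             config = swarm_config(),
                             scenario = scenario_config("plain")) {
  if (length(samples) == 0L) stop("samples must be non-empty", call. = FALSE)
  if (batch_size < 1L) stop("'batch_size' must be >= 1", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  starts <- seq(1L, length(samples), by = batch_size)
  swarm <- NULL
  history <- NULL
  res <- NULL
  for (u in seq_along(starts)) {
    idx <- starts[u]:min(starts[u] + batch_size - 1L, length(samples))
    res <- optimize_unit(samples[idx], config, scenario, swarm)
    swarm <- res$swarm
    hu <- res$history
    hu$unit <- u
    history <- rbind(history, hu[, c("unit", "epoch", "gbest_fitness",
                                     "delta", "tau", "rule")])
  }
  list(params = denormalize_params(res$best), normalized = res$best,
       fitness = res$fitness, history = history)
}
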
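test_that("normalization maps the triplet to the unit cube and back", {
  np <- normalize_params(detector_params(255, 0.3, 511))
  expect_equal(unname(np), c(1, 0.3, 1))
  expect_equal(unname(normalize_params(detector_params(0, 0, 0))), c(0, 0, 0))
  p <- denormalize_params(c(0.5, 0.9, 0.5))
  expect_equal(p$delta, 128L)  # round-half-up
  expect_equal(p$rule, 256L)
  expect_equal(p$tau, 0.9)
  clamped <- denormalize_params(c(1.2, 1.5, -0.1))
  expect_equal(clamped$delta, 255L)
  expect_equal(clamped$rule, 0L)
  expect_lt(clamped$tau, 1)
  # exhaustive round trip over the discrete grid
  deltas <- 0:255
  back_d <- vapply(deltas, function(d)
    denormalize_params(c(d / 255, 0.5, 0))$delta, integer(1))
  expect_identical(back_d, deltas)
  rules <- 0:511
  back_r <- vapply(rules, function(r)
    denormalize_params(c(0, 0.5, r / 511))$rule, integer(1))
  expect_identical(back_r, rules)
})

test_that("velocity update matches the hand-evaluated recurrence", {
  cfg <- swarm_config(omega = 0.05, c1 = 2.1, c2 = 1.2)
  v <- update_velocity(velocity = c(0.1, 0, 0), position = c(0.5, 0.5, 0.5),
                       pbest = c(0.6, 0.5, 0.5), gbest = c(0.7, 0.5, 0.5),
                       config = cfg, r1 = rep(0.5, 3), r2 = rep(0.5, 3))
  expect_equal(v[1], 0.05 * 0.1 + 0.5 * 2.1 * 0.1 + 0.5 * 1.2 * 0.2)
  expect_equal(v[2:3], c(0, 0))
  # attraction vanishes at a consensus point
  cfg1 <- swarm_config(omega = 1, c1 = 0, c2 = 0)
  expect_equal(update_velocity(c(0.2, -0.1, 0), c(0.5, 0.5, 0.5),
                               c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5), cfg1),
               c(0.2, -0.1, 0))
  # clamping to v_max
  cfg2 <- swarm_config(omega = 1, c1 = 0, c2 = 0, v_max = 0.15)
  expect_equal(update_velocity(c(0.5, -0.5, 0), c(0, 0, 0), c(0, 0, 0),
                               c(0, 0, 0), cfg2), c(0.15, -0.15, 0))
})

test_that("position update adds velocity and clamps to the unit cube", {
  expect_equal(update_position(c(0.2, 0.2, 0.2), c(0.1, -0.1, 0)),
               c(0.3, 0.1, 0.2))
  expect_equal(update_position(c(0.9, 0.9, 0.9), c(0.3, 0, 0)),
               c(1, 0.9, 0.9))
  expect_equal(update_position(c(0.1, 0.5, 0.9), c(0, 0, 0)),
               c(0.1, 0.5, 0.9))
})

test_that("fitness is the mean Dice coefficient over the batch", {
  img <- step_image(8, 8)
  p <- detector_params(255, 0.4, 495)
  perfect <- labeled_sample(img, apply_detector(img, p))
  expect_equal(evaluate_fitness(normalize_params(p), list(perfect)), 1)
  # empty prediction against non-empty truth scores 0
  some_truth <- labeled_sample(img, perfect$truth)
  expect_equal(evaluate_fitness(normalize_params(detector_params(100, 0.2, 0)),
                                list(some_truth)), 0)
  # arithmetic mean over two samples with known individual scores
  disjoint <- matrix(0, 8, 8); disjoint[, 1] <- 1
  disjoint[perfect$truth == 1] <- 0
  half <- labeled_sample(img, disjoint)
  expect_equal(evaluate_fitness(normalize_params(p), list(perfect, half)),
               mean(c(1, dsc(apply_detector(img, p), disjoint))))
  # permutation invariance
  expect_equal(evaluate_fitness(normalize_params(p), list(half, perfect)),
               evaluate_fitness(normalize_params(p), list(perfect, half)))
})

test_that("matrix fitness path agrees with scenario-based evaluation", {
  set.seed(7)
  phantoms <- small_phantoms(2, master_seed = 55)
  for (rep in 1:5) {
    p <- random_params()
    fast <- evaluate_fitness(normalize_params(p), phantoms)
    slow <- mean(sapply(phantoms, function(s)
      dsc(apply_detector(s$image, p), s$truth)))
    expect_equal(fast, slow)
  }
})

test_that("optimization is deterministic under a fixed seed", {
  phantoms <- small_phantoms(2, master_seed = 60)
  cfg <- swarm_config(n_particles = 15, epochs_per_unit = 4, seed = 9L)
  a <- optimize_dataset(phantoms, 1, cfg)
  b <- optimize_dataset(phantoms, 1, cfg)
  expect_identical(a$normalized, b$normalized)
  expect_identical(a$history, b$history)
})

test_that("global best never degrades within a unit and positions stay in [0,1]^3", {
  phantoms <- small_phantoms(1, master_seed = 61)
  set.seed(5)
  res <- optimize_unit(phantoms, swarm_config(n_particles = 20,
                                              epochs_per_unit = 8))
  expect_true(all(diff(res$history$gbest_fitness) >= 0))
  expect_true(all(res$swarm$positions >= 0 & res$swarm$positions <= 1))
  expect_true(all(res$best >= 0 & res$best <= 1))
})

test_that("a swarm seeded at a known optimum with no motion stays there", {
  img <- step_image(8, 8)
  p <- detector_params(255, 0.4, 495)
  sample1 <- labeled_sample(img, apply_detector(img, p))
  cfg <- swarm_config(n_particles = 5, epochs_per_unit = 3, omega = 0,
                      c1 = 0, c2 = 0)
  opt <- normalize_params(p)
  swarm <- list(positions = matrix(rep(opt, each = 5), 5, 3),
                velocities = matrix(0, 5, 3))
  set.seed(1)
  res <- optimize_unit(list(sample1), cfg, swarm = swarm)
  expect_equal(unname(res$best), unname(opt))
  expect_equal(res$fitness, 1)
})

test_that("batched protocols partition the samples and reset between units", {
  phantoms <- small_phantoms(5, master_seed = 62)
  cfg <- swarm_config(n_particles = 10, epochs_per_unit = 3, seed = 3L)
  whole <- optimize_dataset(phantoms, batch_size = 5, cfg)
  expect_equal(max(whole$history$unit), 1L)
  per_image <- optimize_dataset(phantoms, batch_size = 1, cfg)
  expect_equal(max(per_image$history$unit), 5L)
  uneven <- optimize_dataset(phantoms, batch_size = 3, cfg)
  expect_equal(max(uneven$history$unit), 2L)  # batches of 3 and 2
  expect_error(optimize_dataset(list(), 1, cfg), "non-empty")
})
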
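# Experiments run here on reduced problem sizes (few images, small
# swarm); the acceptance suite exercises the full designs.

tiny_set <- function(master_seed) small_phantoms(4, master_seed = master_seed)
tiny_params <- detector_params(60, 0.35, 495)

test_that("noise robustness reports one row per variant and level, reproducibly", {
  test_set <- tiny_set(70)
  pv <- list(plain = tiny_params, post = tiny_params, pre_post = tiny_params)
  ex <- run_noise_robustness(test_set, pv, sigma_noise_levels = c(0, 1, 2, 3),
                             seed = 5)
  expect_equal(nrow(ex$table), 3 * 4)
  expect_equal(nrow(ex$per_image), 3 * 4 * 4)
  ex2 <- run_noise_robustness(test_set, pv, sigma_noise_levels = c(0, 1, 2, 3),
                              seed = 5)
  expect_identical(ex$table, ex2$table)
  # internal consistency: aggregate means equal means of per-image values
  for (r in seq_len(nrow(ex$table))) {
    rows <- ex$per_image[ex$per_image$variant == ex$table$variant[r] &
                         ex$per_image$sigma_noise == ex$table$sigma_noise[r], ]
    expect_equal(ex$table$mean_psnr[r], mean(rows$psnr))
    expect_equal(ex$table$mean_ssim[r], mean(rows$ssim))
  }
})

test_that("smoothing sweep covers all levels for both methods with binary outputs", {
  test_set <- tiny_set(71)
  ex <- run_smooth_sweep(test_set, tiny_params,
                         sigma_smooth_levels = c(0, 0.5, 1.5),
                         include_canny = TRUE)
  expect_equal(nrow(ex$table), 3 * 2)
  expect_setequal(unique(ex$table$method), c("ca_pre_post", "canny"))
  # sigma 0 row equals the post scenario by construction
  post_scores <- sapply(test_set, function(s)
    psnr(run_scenario(s$image, tiny_params, scenario_config("post")), s$truth))
  expect_equal(ex$table$mean_psnr[ex$table$method == "ca_pre_post" &
                                  ex$table$sigma_smooth == 0],
               mean(post_scores))
})

test_that("batch-size sweep optimizes at each size and yields valid parameters", {
  train <- tiny_set(72); test_set <- tiny_set(73)
  cfg <- swarm_config(n_particles = 10, epochs_per_unit = 3, seed = 2L)
  ex <- run_batchsize_sweep(train, test_set, batch_sizes = c(1, 2, 4),
                            config = cfg)
  expect_equal(nrow(ex$table), 3)
  expect_true(all(ex$table$delta %in% 0:255))
  expect_true(all(ex$table$rule %in% 0:511))
  expect_true(all(ex$table$tau >= 0 & ex$table$tau < 1))
  expect_true(all(is.finite(ex$table$mean_ssim)))
  expect_error(run_batchsize_sweep(train, test_set, batch_sizes = 10,
                                   config = cfg))
})

test_that("difficulty analysis reports correlations in range, negative on a set degraded with difficulty", {
  # construct a set whose degradation grows with difficulty: increasing
  # noise raises the Sobel mean gradient and damages the detected edges
  base <- small_phantoms(6, master_seed = 74)
  graded <- lapply(seq_along(base), function(i) {
    labeled_sample(inject_noise(base[[i]]$image, 6 * (i - 1), seed = 80 + i),
                   base[[i]]$truth)
  })
  ex <- run_difficulty_analysis(graded, tiny_params, sigma_smooth = 1)
  expect_equal(nrow(ex$per_image), 6)
  expect_true(abs(ex$meta$cor_psnr) <= 1)
  expect_true(abs(ex$meta$cor_ssim) <= 1)
  expect_lt(ex$meta$cor_ssim, 0)
  expect_equal(ex$meta$difficulty_range, diff(range(ex$per_image$difficulty)))
})
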
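# Experiment drivers: noise robustness of the three scenarios, the
# smoothing sweep against the Canny baseline, the batch-size sweep, and
# the difficulty (mean-gradient) analysis. Each returns a
# "caed_experiment" object holding the aggregate table, the per-image
# values it was averaged from, and the seed metadata.

experiment_result <- function(table, per_image, meta) {
  structure(list(table = table, per_image = per_image, meta = meta),
            class = "caed_experiment")
}

#' @export
print.caed_experiment <- function(x, ...) {
  cat(sprintf("CA edge-detection experiment (%s), %d aggregate rows, %d per-image rows\n",
              x$meta$experiment, nrow(x$table), nrow(x$per_image)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

scenario_for_variant <- function(variant, sigma_smooth, min_component_size = 8L) {
  switch(variant,
         plain = scenario_config("plain"),
         post = scenario_config("post", min_component_size = min_component_size),
         pre_post = scenario_config("pre_post", sigma_smooth = sigma_smooth,
                                    min_component_size = min_component_size),
         stop("unknown scenario variant: ", variant, call. = FALSE))
}

score_samples <- function(samples, score_fun) {
  psnr_v <- numeric(length(samples)); ssim_v <- numeric(length(samples))
  for (i in seq_along(samples)) {
    pred <- score_fun(samples[[i]]$image)
    psnr_v[i] <- psnr(pred, samples[[i]]$truth)
    ssim_v[i] <- ssim(pred, samples[[i]]$truth)
  }
  data.frame(image = seq_along(samples), psnr = psnr_v, ssim = ssim_v)
}

#' Noise-robustness experiment
#'
#' Evaluates each scenario variant on the test set and on copies injected
#' with Gaussian noise of increasing standard deviation, and reports the
#' mean PSNR and SSIM per (variant, noise level).
#'
#' @param test_samples List of [labeled_sample()] objects.
#' @param params_by_variant Named list mapping variant names (among
#'   \code{"plain"}, \code{"post"}, \code{"pre_post"}) to
#'   [detector_params()] objects.
#' @param sigma_noise_levels Noise levels; must include 0 (the original
#'   images).
#' @param sigma_smooth Pre-filter standard deviation for the
#'   \code{pre_post} variant.
#' @param seed Integer seed for the injected noise fields.
#' @return A \code{"caed_experiment"} object.
#' @export
run_noise_robustness <- function(test_samples, params_by_variant,
                                 sigma_noise_levels = c(0, 1, 2, 3),
                                 sigma_smooth = 1.5, seed = 1L) {
  stopifnot(0 %in% sigma_noise_levels, length(test_samples) >= 1)
  variants <- names(params_by_variant)
  per <- NULL
  for (v in variants) {
    cfg <- scenario_for_variant(v, sigma_smooth)
    for (lev in sigma_noise_levels) {
      noisy <- lapply(seq_along(test_samples), function(i) {
        s <- test_samples[[i]]
        labeled_sample(inject_noise(s$image, lev, seed = seed + 7919L * i),
                       s$truth)
      })
      rows <- score_samples(noisy, function(img)
        run_scenario(img, params_by_variant[[v]], cfg))
      rows$variant <- v; rows$sigma_noise <- lev
      per <- rbind(per, rows)
    }
  }
  agg <- stats::aggregate(cbind(psnr, ssim) ~ variant + sigma_noise,
                          data = per, FUN = mean)
  names(agg)[3:4] <- c("mean_psnr", "mean_ssim")
  agg <- agg[order(agg$variant, agg$sigma_noise), ]
  experiment_result(agg, per, list(experiment = "noise_robustness", seed = seed))
}

#' Smoothing sweep against the Canny baseline
#'
#' Evaluates the pre_post scenario (and optionally Canny with the same
#' Gaussian sigma) at several pre-filter standard deviations.
#'
#' @param test_samples List of [labeled_sample()] objects.
#' @param params A [detector_params()] object for the CA detector.
#' @param sigma_smooth_levels Pre-filter standard deviations to test.
#' @param include_canny Also run the Canny baseline at each level.
#' @return A \code{"caed_experiment"} object.
#' @export
run_smooth_sweep <- function(test_samples, params,
                             sigma_smooth_levels = c(0, 0.5, 1, 1.25, 1.5),
                             include_canny = TRUE) {
  stopifnot(length(sigma_smooth_levels) >= 1)
  per <- NULL
  for (lev in sigma_smooth_levels) {
    cfg <- if (lev > 0) scenario_config("pre_post", sigma_smooth = lev)
           else scenario_config("post")
    rows <- score_samples(test_samples, function(img)
      run_scenario(img, params, cfg))
    rows$method <- "ca_pre_post"; rows$sigma_smooth <- lev
    per <- rbind(per, rows)
    if (include_canny) {
      rows <- score_samples(test_samples, function(img)
        canny_baseline(img, sigma = lev))
      rows$method <- "canny"; rows$sigma_smooth <- lev
      per <- rbind(per, rows)
    }
  }
  agg <- stats::aggregate(cbind(psnr, ssim) ~ method + sigma_smooth,
                          data = per, FUN = mean)
  names(agg)[3:4] <- c("mean_psnr", "mean_ssim")
  agg <- agg[order(agg$method, agg$sigma_smooth), ]
  experiment_result(agg, per, list(experiment = "smooth_sweep", seed = NA))
}

#' Batch-size sweep
#'
#' For each batch size, optimizes the detector on the training set with
#' [optimize_dataset()] and evaluates the pre_post scenario on the test
#' set.
#'
#' @param train_samples,test_samples Lists of [labeled_sample()] objects.
#' @param batch_sizes Batch sizes to test; each must not exceed the
#'   training-set size.
#' @param config A [swarm_config()]; its seed (offset per batch size)
#'   makes the sweep reproducible.
#' @param sigma_smooth Pre-filter standard deviation used both for
#'   fitness evaluation and at test time.
#' @return A \code{"caed_experiment"} object; the table carries the
#'   optimized triplet per batch size.
#' @export
run_batchsize_sweep <- function(train_samples, test_samples,
                                batch_sizes = c(1, 3, 5, 7, 10, 20),
                                config = swarm_config(seed = 1L),
                                sigma_smooth = 1.5) {
  stopifnot(all(batch_sizes >= 1), all(batch_sizes <= length(train_samples)))
  fit_scenario <- scenario_config("pre_post", sigma_smooth = sigma_smooth)
  test_cfg <- scenario_config("pre_post", sigma_smooth = sigma_smooth)
  per <- NULL; agg <- NULL
  for (k in seq_along(batch_sizes)) {
    bs <- batch_sizes[k]
    cfg_k <- config
    if (!is.null(cfg_k$seed)) cfg_k$seed <- cfg_k$seed + k - 1L
    opt <- optimize_dataset(train_samples, batch_size = bs, config = cfg_k,
                            scenario = fit_scenario)
    rows <- score_samples(test_samples, function(img)
      run_scenario(img, opt$params, test_cfg))
    rows$batch_size <- bs
    per <- rbind(per, rows)
    agg <- rbind(agg, data.frame(batch_size = bs,
                                 mean_psnr = mean(rows$psnr),
                                 mean_ssim = mean(rows$ssim),
                                 train_fitness = opt$fitness,
                                 delta = opt$params$delta,
                                 tau = opt$params$tau,
                                 rule = opt$params$rule))
  }
  experiment_result(agg, per, list(experiment = "batchsize_sweep",
                                   seed = config$seed))
}

#' Difficulty analysis
#'
#' Scores every test image with the pre_post scenario, measures its
#' difficulty as the Sobel mean gradient of the raw image, and reports
#' the Pearson correlations of difficulty with PSNR and with SSIM, plus
#' the median and range of the difficulty scores.
#'
#' @param test_samples At least 3 [labeled_sample()] objects.
#' @param params A [detector_params()] object.
#' @param sigma_smooth Pre-filter standard deviation.
#' @return A \code{"caed_experiment"} object whose \code{meta} carries
#'   \code{cor_psnr}, \code{cor_ssim}, \code{median_difficulty} and
#'   \code{difficulty_range}.
#' @export
run_difficulty_analysis <- function(test_samples, params, sigma_smooth = 1.5) {
  stopifnot(length(test_samples) >= 3)
  cfg <- scenario_config("pre_post", sigma_smooth = sigma_smooth)
  per <- score_samples(test_samples, function(img)
    run_scenario(img, params, cfg))
  per$difficulty <- vapply(test_samples, function(s)
    mean_gradient_difficulty(s$image), numeric(1))
  finite <- is.finite(per$psnr)
  meta <- list(experiment = "difficulty_analysis", seed = NA,
               cor_psnr = pearson_correlation(per$difficulty[finite],
                                              per$psnr[finite]),
               cor_ssim = pearson_correlation(per$difficulty, per$ssim),
               median_difficulty = stats::median(per$difficulty),
               difficulty_range = diff(range(per$difficulty)))
  agg <- data.frame(mean_psnr = mean(per$psnr), mean_ssim = mean(per$ssim),
                    cor_psnr = meta$cor_psnr, cor_ssim = meta$cor_ssim,
                    median_difficulty = meta$median_difficulty,
                    difficulty_range = meta$difficulty_range)
  experiment_result(agg, per, meta)
}
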
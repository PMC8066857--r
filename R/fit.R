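# The modelling interface: caed_fit() optimizes a detector on labeled
# samples and returns a classed object with the usual accessor methods.

#' Fit a cellular-automaton edge detector
#'
#' Optimizes the detector triplet (delta, tau, rule) on a set of labeled
#' samples by particle swarm optimization with Dice-coefficient fitness
#' (see [optimize_dataset()]), and packages the result for prediction on
#' new images.
#'
#' @param samples Non-empty list of [labeled_sample()] objects, or a
#'   single [labeled_sample()].
#' @param batch_size Images per optimization unit; 1 is the per-image
#'   protocol, \code{length(samples)} a single batch.
#' @param control A [swarm_config()] object.
#' @param scenario A [scenario_config()] object; governs both the fitness
#'   path during optimization and the default prediction pipeline.
#' @return An object of class \code{"caed"} with elements \code{params},
#'   \code{normalized}, \code{fitness}, \code{history}, \code{control},
#'   \code{scenario}, \code{n_samples} and \code{call}.
#' @examples
#' set.seed(1)
#' train <- make_optimization_set(3, "low", master_seed = 7, size = 64)
#' fit <- caed_fit(train, batch_size = 3,
#'                 control = swarm_config(n_particles = 20,
#'                                        epochs_per_unit = 5, seed = 1))
#' coef(fit)
#' edges <- predict(fit, train[[1]]$image)
#' @export
caed_fit <- function(samples, batch_size = 1L, control = swarm_config(),
                     scenario = scenario_config("plain")) {
  if (inherits(samples, "labeled_sample")) samples <- list(samples)
  opt <- optimize_dataset(samples, batch_size = batch_size,
                          config = control, scenario = scenario)
  structure(list(params = opt$params, normalized = opt$normalized,
                 fitness = opt$fitness, history = opt$history,
                 control = control, scenario = scenario,
                 n_samples = length(samples), call = match.call()),
            class = "caed")
}

#' @export
print.caed <- function(x, ...) {
  cat("Cellular-automaton edge detector (PSO-optimized)\n")
  cat(sprintf("  delta = %d, tau = %.4f, rule = %d\n",
              x$params$delta, x$params$tau, x$params$rule))
  cat(sprintf("  final-unit training DSC = %.4f (%d samples, batch size %d, %d units)\n",
              x$fitness, x$n_samples,
              ceiling(x$n_samples / max(x$history$unit)), max(x$history$unit)))
  invisible(x)
}

#' @export
coef.caed <- function(object, ...) {
  c(delta = object$params$delta, tau = object$params$tau,
    rule = object$params$rule)
}

#' Predict edge maps from a fitted detector
#'
#' @param object A \code{"caed"} fit.
#' @param newdata A numeric image matrix, a [labeled_sample()], or a list
#'   of either.
#' @param scenario Pipeline to apply; defaults to the fit's scenario.
#' @param ... Unused.
#' @return A binary edge map, or a list of them when \code{newdata} is a
#'   list.
#' @export
predict.caed <- function(object, newdata, scenario = object$scenario, ...) {
  one <- function(x) {
    img <- if (inherits(x, "labeled_sample")) x$image else x
    run_scenario(img, object$params, scenario)
  }
  if (is.list(newdata) && !inherits(newdata, "labeled_sample")) {
    lapply(newdata, one)
  } else {
    one(newdata)
  }
}

#' @export
summary.caed <- function(object, ...) {
  h <- object$history
  per_unit <- do.call(rbind, lapply(split(h, h$unit), function(d) {
    data.frame(unit = d$unit[1L],
               initial_fitness = d$gbest_fitness[d$epoch == 0L],
               final_fitness = max(d$gbest_fitness),
               delta = d$delta[nrow(d)], tau = d$tau[nrow(d)],
               rule = d$rule[nrow(d)])
  }))
  structure(list(params = object$params, fitness = object$fitness,
                 per_unit = per_unit, control = object$control,
                 scenario = object$scenario),
            class = "summary.caed")
}

#' @export
print.summary.caed <- function(x, ...) {
  cat("PSO-optimized CA edge detector\n\n")
  print(x$params)
  cat(sprintf("\nScenario: %s (fitness on %s map)\n", x$scenario$scenario,
              if (x$scenario$fitness_post) "post-processed" else "plain"))
  cat(sprintf("Swarm: %d particles, %d epochs/unit, omega = %.2f, c1 = %.1f, c2 = %.1f\n\n",
              x$control$n_particles, x$control$epochs_per_unit,
              x$control$omega, x$control$c1, x$control$c2))
  cat("Per-unit global best:\n")
  print(x$per_unit, row.names = FALSE)
  invisible(x)
}

#' Plot the optimization trajectory of a fitted detector
#'
#' Global-best Dice fitness against cumulative epoch, with unit
#' boundaries (global-best resets) marked.
#'
#' @param x A \code{"caed"} fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.caed <- function(x, ...) {
  h <- x$history
  epochs_per_unit <- max(h$epoch)
  t <- (h$unit - 1L) * (epochs_per_unit + 1L) + h$epoch
  graphics::plot(t, h$gbest_fitness, type = "s", xlab = "cumulative epoch",
                 ylab = "global-best DSC", ylim = c(0, 1), ...)
  if (max(h$unit) > 1L) {
    graphics::abline(v = (seq_len(max(h$unit) - 1L)) * (epochs_per_unit + 1L),
                     lty = 3, col = "grey50")
  }
  invisible(x)
}
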
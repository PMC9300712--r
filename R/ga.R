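#' Chromosome fitness from predicted removal
#'
#' The fitness score of a candidate solution is
#' \eqn{\epsilon = 1 - 1/\hat{y}} where \eqn{\hat{y}} is the surrogate's
#' predicted percentage removal; it is strictly increasing in the
#' prediction, so maximising fitness maximises removal. Non-positive
#' predictions get the worst representable fitness instead of an error, so
#' the corresponding individuals are simply selected against.
#'
#' @param y_pred numeric vector of predicted removals (percent).
#' @return numeric fitness vector.
#' @examples
#' ga_fitness(c(1, 50, 100))   # 0, 0.98, 0.99
#' @export
ga_fitness <- function(y_pred) {
  eps <- ifelse(y_pred > 0, 1 - 1 / y_pred, -Inf)
  eps[!is.finite(y_pred) | !is.finite(eps)] <- -.Machine$double.xmax
  eps
}

#' Genetic-algorithm configuration
#'
#' Defaults follow the study's optimiser settings: population 100, elite
#' count 20, single-point crossover with probability 0.8, Gaussian mutation,
#' 100 generations, roulette (fitness-proportional) selection.
#'
#' @param population_size number of individuals per generation.
#' @param elite_count individuals copied unchanged to the next generation.
#' @param crossover_prob probability a selected pair undergoes single-point
#'   crossover.
#' @param generations number of generations.
#' @param mutation_sd per-gene Gaussian mutation standard deviation in
#'   actual units; \code{NULL} (default) means 0.1 x (upper - lower).
#' @param mutation_shrink fraction by which the mutation scale decays
#'   linearly over the run (1 = anneal to zero by the final generation, the
#'   Gaussian-mutation convention; 0 = constant scale).
#' @param bounds 2 x 4 matrix (rows \code{lower}, \code{upper}) or list with
#'   \code{lower}, \code{upper} length-4 vectors, actual units.
#' @return list of class \code{ga_config}.
#' @export
ga_config <- function(population_size = 100, elite_count = 20,
                      crossover_prob = 0.8, generations = 100,
                      mutation_sd = NULL, mutation_shrink = 1,
                      bounds = default_ga_bounds()) {
  if (is.list(bounds) && !is.data.frame(bounds))
    bounds <- rbind(lower = bounds$lower, upper = bounds$upper)
  stopifnot(nrow(bounds) == 2, ncol(bounds) == 4,
            all(is.finite(bounds)), all(bounds[1, ] < bounds[2, ]),
            elite_count < population_size,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_shrink >= 0, mutation_shrink <= 1)
  if (is.null(mutation_sd)) mutation_sd <- 0.1 * (bounds[2, ] - bounds[1, ])
  mutation_sd <- rep_len(mutation_sd, 4)
  structure(list(population_size = as.integer(population_size),
                 elite_count = as.integer(elite_count),
                 crossover_prob = crossover_prob,
                 generations = as.integer(generations),
                 mutation_sd = mutation_sd,
                 mutation_shrink = mutation_shrink, bounds = bounds),
            class = "ga_config")
}

#' Factor bounds of the As(III) biosorption search space
#'
#' Dose 0.1-1.3 g/L, pH 2-10, temperature 25-45 degC, initial As(III)
#' concentration 0.1-1.3 mg/L — the box the study constrained its
#' optimisation to.
#'
#' @return 2 x 4 matrix with rows \code{lower}, \code{upper}.
#' @export
default_ga_bounds <- function() {
  rbind(lower = c(0.1, 2, 25, 0.1), upper = c(1.3, 10, 45, 1.3))
}

clip_to_bounds <- function(pop, bounds) {
  pop <- pmax(pop, matrix(bounds[1, ], nrow(pop), 4, byrow = TRUE))
  pmin(pop, matrix(bounds[2, ], nrow(pop), 4, byrow = TRUE))
}

# roulette selection over min-shifted fitness; all-equal fitness degenerates
# to uniform sampling
roulette_pick <- function(fitness, n) {
  w <- fitness - min(fitness) + 1e-12
  if (!any(w > 0) || !all(is.finite(w))) w <- rep(1, length(fitness))
  sample.int(length(fitness), n, replace = TRUE, prob = w)
}

#' One genetic-algorithm generation
#'
#' Elites (by fitness) are copied unchanged; the remainder of the next
#' generation is produced by roulette selection of parents, single-point
#' crossover of the 4-gene chromosomes with probability
#' \code{config$crossover_prob}, and per-gene Gaussian mutation clipped to
#' the bounds.
#'
#' @param population n x 4 matrix of individuals (actual units).
#' @param fitness numeric fitness vector, one value per row.
#' @param config a \code{\link{ga_config}}.
#' @param progress fraction of the run already elapsed (0 at the first
#'   generation), used to anneal the mutation scale by
#'   \code{config$mutation_shrink}.
#' @return next-generation population matrix of the same size.
#' @export
ga_evolve <- function(population, fitness, config, progress = 0) {
  stopifnot(is.matrix(population), nrow(population) == length(fitness),
            nrow(population) == config$population_size,
            progress >= 0, progress <= 1)
  sd_eff <- config$mutation_sd * (1 - config$mutation_shrink * progress)
  n <- nrow(population)
  ord <- order(fitness, decreasing = TRUE)
  nxt <- population[ord[seq_len(config$elite_count)], , drop = FALSE]
  need <- n - config$elite_count
  parents <- population[roulette_pick(fitness, 2 * need), , drop = FALSE]
  children <- matrix(NA_real_, need, 4)
  for (k in seq_len(need)) {
    p1 <- parents[2 * k - 1, ]; p2 <- parents[2 * k, ]
    child <- p1
    if (runif(1) < config$crossover_prob) {
      cut <- sample.int(3, 1)            # crossover point between genes
      child <- c(p1[seq_len(cut)], p2[(cut + 1):4])
    }
    children[k, ] <- child + rnorm(4, 0, sd_eff)
  }
  rbind(nxt, clip_to_bounds(children, config$bounds))
}

#' Maximise a surrogate's predicted removal by genetic algorithm
#'
#' Evolves a random initial population inside the factor bounds for
#' \code{config$generations} generations and reports the best individual
#' ever evaluated. The surrogate may be an \code{\link{mlp_network}}, a
#' \code{\link{quadratic_surface}} (evaluated in actual units via its factor
#' specs), or any function mapping an n x 4 actual-unit matrix to predicted
#' removals.
#'
#' @param surrogate predictor as described above.
#' @param config a \code{\link{ga_config}}.
#' @param seed integer seed; fixes the whole run.
#' @return object of class \code{ga_result}: list with \code{best_x}
#'   (actual units), \code{best_prediction} (percent),
#'   \code{best_fitness}, and \code{fitness_history} (best-so-far fitness
#'   per generation, non-decreasing under elitism).
#' @examples
#' sur <- function(X) 100 - (X[, 1] - 0.7)^2 - (X[, 2] - 7)^2
#' ga_optimize(sur, ga_config(generations = 30), seed = 1)$best_x
#' @export
ga_optimize <- function(surrogate, config = ga_config(), seed = NULL) {
  predict_fn <- surrogate_fn(surrogate)
  with_seed(seed, function() {
    bounds <- config$bounds
    pop <- matrix(runif(config$population_size * 4,
                        min = rep(bounds[1, ], each = config$population_size),
                        max = rep(bounds[2, ], each = config$population_size)),
                  ncol = 4)
    best <- list(fitness = -Inf)
    history <- numeric(config$generations)
    for (g in seq_len(config$generations)) {
      pred <- predict_fn(pop)
      fit <- ga_fitness(pred)
      i <- which.max(fit)
      if (fit[i] > best$fitness)
        best <- list(x = pop[i, ], prediction = pred[i], fitness = fit[i])
      history[g] <- best$fitness
      pop <- ga_evolve(pop, fit, config,
                       progress = (g - 1) / config$generations)
    }
    structure(list(best_x = unname(best$x),
                   best_prediction = best$prediction,
                   best_fitness = best$fitness,
                   fitness_history = history,
                   config = config),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(paste0("<ga_result> best prediction %.2f%% at dose %.3f g/L,",
                     " pH %.2f, %.1f degC, %.3f mg/L\n"),
              x$best_prediction, x$best_x[1], x$best_x[2], x$best_x[3],
              x$best_x[4]))
  invisible(x)
}

#' Multi-restart genetic-algorithm optimisation
#'
#' Runs \code{\link{ga_optimize}} \code{restarts} times with seeds derived
#' from \code{seed} and returns the consensus (highest-fitness) result,
#' mirroring the practice of reiterating the optimiser and keeping the
#' recurring best solution.
#'
#' @inheritParams ga_optimize
#' @param restarts number of independent runs (default 10).
#' @return list with \code{best} (the winning \code{ga_result}) and
#'   \code{runs} (all restarts).
#' @export
ga_optimize_multi <- function(surrogate, config = ga_config(),
                              restarts = 10, seed = NULL) {
  seeds <- if (is.null(seed)) rep(list(NULL), restarts)
           else as.list(seed + seq_len(restarts) - 1L)
  runs <- lapply(seeds, function(s) ga_optimize(surrogate, config, seed = s))
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "best_fitness"))]]
  list(best = best, runs = runs)
}

surrogate_fn <- function(surrogate) {
  if (is.function(surrogate)) return(surrogate)
  if (inherits(surrogate, "mlp_network"))
    return(function(X) predict(surrogate, X))
  if (inherits(surrogate, "quadratic_surface")) {
    specs <- surrogate$factor_specs
    return(function(X) {
      coded <- mapply(function(j, spec) code_factor(X[, j], spec),
                      1:4, specs)
      predict(surrogate, matrix(coded, ncol = 4))
    })
  }
  stop("surrogate must be a function, mlp_network or quadratic_surface",
       call. = FALSE)
}
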
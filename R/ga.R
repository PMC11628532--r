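#' Genetic-algorithm configuration
#'
#' Hyperparameters of the weight-selection GA. Defaults (population 30, 50
#' generations, tournament selection of size 3, crossover rate 0.9, mutation
#' rate 0.2, mutation scale 0.05, elitism 1) are conventional small-GA
#' settings; all are exposed because none is canonical.
#'
#' @param population_size number of chromosomes per generation (>= 2).
#' @param max_generations generation cap.
#' @param selection `"tournament"` or `"roulette"`.
#' @param tournament_size tournament size when `selection = "tournament"`.
#' @param crossover_rate probability a selected pair is crossed rather than
#'   copied.
#' @param mutation_rate per-chromosome probability of one mutation event.
#' @param mutation_scale half-width of the uniform perturbation applied to
#'   the mutated coordinate.
#' @param elitism number of best chromosomes copied unchanged into the next
#'   generation; >= 1 guarantees a non-decreasing best-fitness trace.
#' @param fitness_target optional early-stop threshold on best fitness.
#' @param seed optional integer seed; if supplied, the run is reproducible.
#' @return a list of class `"ga_config"`.
#' @export
ga_config <- function(population_size = 30L, max_generations = 50L,
                      selection = c("tournament", "roulette"),
                      tournament_size = 3L, crossover_rate = 0.9,
                      mutation_rate = 0.2, mutation_scale = 0.05,
                      elitism = 1L, fitness_target = NULL, seed = NULL) {
  selection <- match.arg(selection)
  population_size <- as.integer(population_size)
  if (population_size < 2L) stop("population_size must be >= 2")
  if (max_generations < 1L) stop("max_generations must be >= 1")
  if (crossover_rate < 0 || crossover_rate > 1) stop("crossover_rate must be in [0, 1]")
  if (mutation_rate < 0 || mutation_rate > 1) stop("mutation_rate must be in [0, 1]")
  if (mutation_scale <= 0) stop("mutation_scale must be positive")
  elitism <- as.integer(elitism)
  if (elitism < 0L || elitism >= population_size) stop("need 0 <= elitism < population_size")
  if (tournament_size < 1L) stop("tournament_size must be >= 1")
  structure(list(population_size = population_size,
                 max_generations = as.integer(max_generations),
                 selection = selection, tournament_size = as.integer(tournament_size),
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 mutation_scale = mutation_scale, elitism = elitism,
                 fitness_target = fitness_target, seed = seed),
            class = "ga_config")
}

#' Initial GA population on the weight simplex
#'
#' Each chromosome is drawn from the symmetric Dirichlet(1) distribution —
#' uniform on the simplex — via normalized Exp(1) variates.
#'
#' @param k number of models (simplex dimension), >= 2.
#' @param config a [ga_config()].
#' @return list of `population_size` numeric weight vectors.
#' @export
init_population <- function(k, config = ga_config()) {
  if (k < 2L) stop("need at least 2 models")
  lapply(seq_len(config$population_size), function(i) {
    g <- stats::rexp(k)
    g / sum(g)
  })
}

#' GA fitness: ensemble accuracy under given fusion weights
#'
#' The fitness of a weight vector is the overall accuracy of the argmax
#' predictions of the weighted-average ensemble against the bundle's labels.
#'
#' @param weights simplex weight vector of length `bundle$n_models`.
#' @param bundle a [model_bundle()].
#' @return accuracy in `[0, 1]`.
#' @export
ga_fitness <- function(weights, bundle) {
  fused <- fuse_weighted(bundle, weights)
  mean(predict_classes(fused) == bundle$labels)
}

#' Parent selection
#'
#' Tournament: the fittest of `tournament_size` chromosomes drawn uniformly
#' with replacement. Roulette: a draw with probability proportional to
#' fitness, falling back to a uniform draw when every fitness is 0.
#'
#' @param population list of weight vectors.
#' @param fitnesses numeric vector of evaluated fitnesses.
#' @param config a [ga_config()].
#' @return index of the selected chromosome.
#' @export
ga_select <- function(population, fitnesses, config = ga_config()) {
  n <- length(population)
  if (n == 0L) stop("empty population")
  if (config$selection == "tournament") {
    idx <- sample.int(n, size = config$tournament_size, replace = TRUE)
    idx[which.max(fitnesses[idx])]
  } else {
    tot <- sum(fitnesses)
    if (tot <= 0) sample.int(n, 1L)
    else sample.int(n, 1L, prob = fitnesses / tot)
  }
}

#' Coordinate-exchange crossover with simplex repair
#'
#' Offspring swap a random non-empty proper subset of coordinates between
#' the two parents (for K = 2 this is exactly the classic exchange producing
#' raw offspring `(a1, b2)` and `(a2, b1)`), then each offspring is divided
#' by its coordinate sum to return to the simplex. A raw sum of 0 resets
#' that offspring to uniform weights.
#'
#' @param p1,p2 parent weight vectors of the same length.
#' @param swap optional logical mask of coordinates to take from the *other*
#'   parent; drawn at random when `NULL` (each pattern of the K-2 valid
#'   non-trivial masks equally likely for K = 2, uniform over proper
#'   non-empty subsets generally).
#' @return list of two simplex weight vectors.
#' @export
ga_crossover <- function(p1, p2, swap = NULL) {
  k <- length(p1)
  if (length(p2) != k) stop("parents differ in length")
  if (is.null(swap)) {
    repeat {
      swap <- stats::runif(k) < 0.5
      if (any(swap) && !all(swap)) break
    }
  }
  raw1 <- ifelse(swap, p2, p1)
  raw2 <- ifelse(swap, p1, p2)
  repair <- function(w) {
    s <- sum(w)
    if (s <= 0) rep(1 / k, k) else w / s
  }
  list(repair(raw1), repair(raw2))
}

#' Simplex-preserving mutation
#'
#' With probability `mutation_rate` one coordinate i is perturbed by
#' `delta ~ Uniform(-mutation_scale, +mutation_scale)`, clipped so the
#' coordinate stays in `[0, 1]`, and the remaining coordinates are rescaled
#' so the vector sums to 1 again (for K = 2 this is the complementary update
#' `a -> a + delta`, `b -> b - delta`). When the remaining coordinates sum
#' to 0 the leftover mass is spread uniformly over them.
#'
#' @param w simplex weight vector.
#' @param config a [ga_config()].
#' @return mutated simplex weight vector.
#' @export
ga_mutate <- function(w, config = ga_config()) {
  if (stats::runif(1L) >= config$mutation_rate) return(w)
  k <- length(w)
  i <- sample.int(k, 1L)
  delta <- stats::runif(1L, -config$mutation_scale, config$mutation_scale)
  new_i <- min(1, max(0, w[i] + delta))
  rest <- sum(w[-i])
  if (rest > 0) {
    w[-i] <- w[-i] * (1 - new_i) / rest
  } else {
    w[-i] <- (1 - new_i) / (k - 1L)
  }
  w[i] <- new_i
  w / sum(w)  # absorb rounding drift; keeps the simplex to < 1e-15
}

#' Select ensemble fusion weights with a genetic algorithm
#'
#' Runs a generational GA over simplex-constrained fusion weights with
#' ensemble accuracy as the fitness: initial Dirichlet(1) population,
#' tournament or roulette parent selection, coordinate-exchange crossover
#' with simplex repair, simplex-preserving mutation, and elitism. Terminates
#' at `max_generations` or as soon as the best fitness reaches
#' `fitness_target`. Fitness ties are resolved toward the earlier-evaluated
#' chromosome, so runs are fully reproducible given the seed.
#'
#' @param bundle a [model_bundle()] of K >= 2 aligned probability matrices
#'   with labels; fitness is evaluated on exactly this bundle (any
#'   train/validation split is the caller's responsibility).
#' @param config a [ga_config()].
#' @param seed integer seed; overrides `config$seed` when given.
#' @return an object of class `"ga_fuse"`; see Details. Methods:
#'   [coef.ga_fuse()] (best weights), [predict.ga_fuse()] (fused
#'   probabilities or classes), `fitted()`, `plot()` (fitness trace),
#'   `print()` and `summary()`.
#' @details The returned object contains `weights` (best weight vector,
#'   named by model), `fitness` (its ensemble accuracy), `trace` (data frame
#'   of per-generation best and mean fitness, non-decreasing in `best` when
#'   `elitism >= 1`), `generations` run, `termination` reason
#'   (`"max_generations"` or `"fitness_target"`), `seed`, `config`, and the
#'   training `bundle`.
#' @examples
#' b <- simulate_bundle(scenario_config(n_samples = 120, n_classes = 4,
#'                                      model_accuracies = c(0.7, 0.7),
#'                                      seed = 1))
#' fit <- ga_fuse(b, ga_config(max_generations = 10), seed = 1)
#' coef(fit)
#' @export
ga_fuse <- function(bundle, config = ga_config(), seed = config$seed) {
  stopifnot(inherits(bundle, "model_bundle"), inherits(config, "ga_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  k <- bundle$n_models
  pop <- init_population(k, config)
  fit <- vapply(pop, ga_fitness, numeric(1L), bundle = bundle)
  best_i <- which.max(fit)  # which.max takes the first maximum: earlier wins
  best_w <- pop[[best_i]]; best_f <- fit[best_i]
  trace_best <- best_f
  trace_mean <- mean(fit)
  gen <- 0L
  termination <- "max_generations"
  if (!is.null(config$fitness_target) && best_f >= config$fitness_target) {
    termination <- "fitness_target"
  } else {
    for (gen in seq_len(config$max_generations)) {
      newpop <- list()
      if (config$elitism > 0L) {
        # stable order: earlier-evaluated chromosomes win fitness ties
        elite <- order(-fit)[seq_len(config$elitism)]
        newpop <- pop[sort(elite)]
      }
      while (length(newpop) < config$population_size) {
        i1 <- ga_select(pop, fit, config)
        i2 <- ga_select(pop, fit, config)
        if (stats::runif(1L) < config$crossover_rate) {
          off <- ga_crossover(pop[[i1]], pop[[i2]])
        } else {
          off <- list(pop[[i1]], pop[[i2]])
        }
        for (o in off) {
          if (length(newpop) < config$population_size) {
            newpop[[length(newpop) + 1L]] <- ga_mutate(o, config)
          }
        }
      }
      pop <- newpop
      fit <- vapply(pop, ga_fitness, numeric(1L), bundle = bundle)
      gi <- which.max(fit)
      if (fit[gi] > best_f) {  # strict: ties keep the earlier chromosome
        best_f <- fit[gi]; best_w <- pop[[gi]]
      }
      trace_best <- c(trace_best, best_f)
      trace_mean <- c(trace_mean, mean(fit))
      if (!is.null(config$fitness_target) && best_f >= config$fitness_target) {
        termination <- "fitness_target"
        break
      }
    }
  }
  nms <- names(bundle$matrices)
  if (is.null(nms)) nms <- paste0("model_", seq_len(k))
  names(best_w) <- nms
  out <- list(weights = best_w, fitness = best_f,
              trace = data.frame(generation = seq_along(trace_best) - 1L,
                                 best_fitness = trace_best,
                                 mean_fitness = trace_mean),
              generations = gen, termination = termination,
              seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
              config = config, bundle = bundle)
  class(out) <- "ga_fuse"
  out
}

#' @export
print.ga_fuse <- function(x, ...) {
  cat("GA-selected ensemble fusion weights\n")
  cat("  weights:", paste(sprintf("%s = %.4f", names(x$weights), x$weights),
                          collapse = ", "), "\n")
  cat(sprintf("  ensemble accuracy (fitness): %.4f\n", x$fitness))
  cat(sprintf("  generations: %d (%s), seed: %s\n", x$generations,
              x$termination, ifelse(is.na(x$seed), "none", x$seed)))
  invisible(x)
}

#' @export
summary.ga_fuse <- function(object, ...) {
  print(object)
  b <- object$bundle
  cat("  standalone accuracies:\n")
  for (k in seq_len(b$n_models)) {
    cat(sprintf("    %-12s %.4f\n", names(object$weights)[k],
                mean(predict_classes(b$matrices[[k]]) == b$labels)))
  }
  eq <- ga_fitness(rep(1 / b$n_models, b$n_models), b)
  cat(sprintf("  equal-weight ensemble accuracy: %.4f\n", eq))
  invisible(object)
}

#' Best fusion weights of a fitted GA run
#' @param object a `ga_fuse` object.
#' @param ... unused.
#' @export
coef.ga_fuse <- function(object, ...) object$weights

#' Predict from a fitted GA fusion
#'
#' Applies the selected weights to a (new) bundle and returns either the
#' fused probability matrix or the hard class predictions.
#'
#' @param object a `ga_fuse` object.
#' @param newdata a `model_bundle` with the same models in the same order;
#'   defaults to the training bundle.
#' @param type `"class"` (0-based argmax labels) or `"prob"` (fused matrix).
#' @param ... unused.
#' @export
predict.ga_fuse <- function(object, newdata = object$bundle,
                            type = c("class", "prob"), ...) {
  type <- match.arg(type)
  w <- unname(object$weights)
  fused <- fuse_weighted(newdata, w)
  if (type == "prob") fused else predict_classes(fused)
}

#' @export
fitted.ga_fuse <- function(object, ...) predict(object, type = "prob")

#' Plot the GA best/mean fitness trace
#' @param x a `ga_fuse` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ga_fuse <- function(x, ...) {
  tr <- x$trace
  graphics::plot(tr$generation, tr$best_fitness, type = "s", lwd = 2,
                 xlab = "generation", ylab = "ensemble accuracy",
                 ylim = range(c(tr$best_fitness, tr$mean_fitness)),
                 main = "GA fitness trace", ...)
  graphics::lines(tr$generation, tr$mean_fitness, lty = 2, col = "grey40")
  graphics::legend("bottomright", c("best", "population mean"),
                   lty = c(1, 2), lwd = c(2, 1), col = c("black", "grey40"),
                   bty = "n")
  invisible(x)
}

#' Exhaustive grid-search oracle for fusion weights
#'
#' Evaluates ensemble accuracy on every simplex grid point with spacing
#' `step` and returns the best. Exact and deterministic; intended as an
#' independent check on the GA for small K. Ties go to the
#' lexicographically smallest weight vector.
#'
#' @param bundle a [model_bundle()] with K = 2 or K = 3 models.
#' @param step grid spacing in `(0, 0.5]`.
#' @return list with `weights` (best grid point), `fitness` (its accuracy),
#'   `grid` (data frame of every grid point and its fitness).
#' @export
grid_search_weights <- function(bundle, step = 0.01) {
  stopifnot(inherits(bundle, "model_bundle"))
  k <- bundle$n_models
  if (k > 3L) stop("grid search supported for K = 2 or 3 only")
  if (step <= 0 || step > 0.5) stop("step must be in (0, 0.5]")
  ticks <- seq(0, 1, by = step)
  if (ticks[length(ticks)] < 1) ticks <- c(ticks, 1)
  if (k == 2L) {
    pts <- lapply(ticks, function(a) c(a, 1 - a))
  } else {
    pts <- list()
    for (a in ticks) for (b in ticks[ticks <= 1 - a + 1e-12]) {
      pts[[length(pts) + 1L]] <- c(a, min(b, 1 - a), max(0, 1 - a - b))
    }
  }
  # lexicographic enumeration so that the first maximum is the smallest point
  ord <- do.call(order, as.data.frame(t(vapply(pts, identity, numeric(k)))))
  pts <- pts[ord]
  fits <- vapply(pts, ga_fitness, numeric(1L), bundle = bundle)
  best <- which.max(fits)
  grid <- as.data.frame(t(vapply(pts, identity, numeric(k))))
  names(grid) <- paste0("w", seq_len(k))
  grid$fitness <- fits
  list(weights = pts[[best]], fitness = fits[best], grid = grid)
}

#' Exact maximum attainable two-model fusion accuracy
#'
#' For K = 2 the fused argmax prediction of each sample changes only at a
#' finite set of breakpoints of the mixing weight `a` in `w = (a, 1 - a)`:
#' the values where two classes' fused probabilities tie. Ensemble accuracy
#' is therefore piecewise constant in `a`, and its exact maximum over the
#' whole interval `[0, 1]` is found by evaluating the fitness at every
#' breakpoint and at the midpoint of every interval between consecutive
#' breakpoints. This is the exhaustive oracle a grid search only
#' approximates: a grid of any finite step can miss plateaus narrower than
#' the step.
#'
#' @param bundle a [model_bundle()] with exactly 2 models.
#' @return list with `max_accuracy`, the achieving `weight` (first maximal
#'   candidate in increasing `a` order) and the number of `candidates`
#'   evaluated.
#' @export
exact_max_accuracy <- function(bundle) {
  stopifnot(inherits(bundle, "model_bundle"))
  if (bundle$n_models != 2L) stop("exact breakpoint enumeration supports K = 2 only")
  P1 <- unclass(bundle$matrices[[1L]])
  P2 <- unclass(bundle$matrices[[2L]])
  y1 <- bundle$labels + 1L
  n <- nrow(P1); C <- ncol(P1)
  # fused_y - fused_c = a * (d1) + (1 - a) * (d2) crosses 0 at
  # a = d2 / (d2 - d1) whenever d1, d2 differ in sign
  breaks <- numeric(0)
  for (cc in seq_len(C)) {
    d1 <- P1[cbind(seq_len(n), y1)] - P1[, cc]
    d2 <- P2[cbind(seq_len(n), y1)] - P2[, cc]
    denom <- d2 - d1
    ok <- abs(denom) > 0 & cc != y1
    r <- d2[ok] / denom[ok]
    breaks <- c(breaks, r[r > 0 & r < 1])
  }
  breaks <- sort(unique(breaks))
  cand <- unique(c(0, breaks, 1,
                   (c(0, breaks) + c(breaks, 1)) / 2))
  cand <- sort(cand)
  fits <- vapply(cand, function(a) ga_fitness(c(a, 1 - a), bundle), numeric(1L))
  best <- which.max(fits)
  list(max_accuracy = fits[best], weight = c(cand[best], 1 - cand[best]),
       candidates = length(cand))
}
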
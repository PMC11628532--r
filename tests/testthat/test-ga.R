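test_that("config validation enforces the population and rate bounds", {
  expect_error(ga_config(population_size = 1), "population_size")
  expect_error(ga_config(elitism = 30), "elitism")
  expect_error(ga_config(mutation_rate = 1.2), "mutation_rate")
  expect_error(ga_config(mutation_scale = 0), "mutation_scale")
})

test_that("initial population is uniform on the simplex and seed-reproducible", {
  cfg <- ga_config()
  expect_error(init_population(1, cfg), "at least 2")
  set.seed(5)
  pop <- init_population(4, cfg)
  expect_length(pop, cfg$population_size)
  for (w in pop) {
    expect_true(all(w >= 0 & w <= 1))
    expect_lt(abs(sum(w) - 1), 1e-9)
  }
  set.seed(5)
  expect_identical(init_population(4, cfg), pop)
})

test_that("fitness at boundary weights equals the standalone accuracy", {
  b <- simulate_bundle(scenario_config(n_samples = 200, n_classes = 4,
                                       model_accuracies = c(0.7, 0.5),
                                       sharpness = 100, seed = 3))
  a1 <- mean(predict_classes(b$matrices[[1]]) == b$labels)
  a2 <- mean(predict_classes(b$matrices[[2]]) == b$labels)
  expect_equal(ga_fitness(c(1, 0), b), a1)
  expect_equal(ga_fitness(c(0, 1), b), a2)
  # identical matrices: fitness constant in the weights
  bi <- model_bundle(list(m1 = b$matrices[[1]], m2 = b$matrices[[1]]),
                     labels = b$labels)
  set.seed(9)
  for (i in 1:10) {
    g <- rgamma(2, 1); w <- g / sum(g)
    expect_equal(ga_fitness(w, bi), a1)
  }
})

test_that("tournament selection matches the exact enumeration probability", {
  # fitnesses (0.9, 0.1, 0.1, 0.1), tournament size 3 drawn WITH replacement:
  # best chromosome selected unless all 3 draws avoid it: 1 - (3/4)^3
  pop <- list(c(1, 0), c(0.5, 0.5), c(0.4, 0.6), c(0.3, 0.7))
  fit <- c(0.9, 0.1, 0.1, 0.1)
  cfg <- ga_config(tournament_size = 3)
  set.seed(21)
  picks <- replicate(4000, ga_select(pop, fit, cfg))
  p_hat <- mean(picks == 1L)
  p_exact <- 1 - (3 / 4)^3
  expect_lt(abs(p_hat - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 4000))
  # dominance: tournament of the whole population always picks the best
  cfg_all <- ga_config(tournament_size = 50)
  expect_true(all(replicate(50, ga_select(pop, fit, cfg_all)) == 1L))
  # roulette with all-zero fitness falls back to a uniform draw
  cfg_r <- ga_config(selection = "roulette")
  set.seed(22)
  picks_r <- replicate(4000, ga_select(pop, c(0, 0, 0, 0), cfg_r))
  expect_gt(min(table(factor(picks_r, levels = 1:4))), 4000 / 4 * 0.8)
  expect_error(ga_select(list(), numeric(0), cfg), "empty")
})

test_that("crossover exchanges coordinates and repairs to the simplex", {
  off <- ga_crossover(c(0.8, 0.2), c(0.3, 0.7), swap = c(FALSE, TRUE))
  expect_equal(off[[1]], c(0.8, 0.7) / 1.5)
  expect_equal(off[[2]], c(0.3, 0.2) / 0.5)
  # identical parents are a fixed point
  off_id <- ga_crossover(c(0.6, 0.4), c(0.6, 0.4))
  expect_equal(off_id[[1]], c(0.6, 0.4))
  expect_equal(off_id[[2]], c(0.6, 0.4))
  # degenerate raw sum 0 resets to uniform
  off_deg <- ga_crossover(c(1, 0), c(0, 1), swap = c(FALSE, TRUE))
  expect_equal(off_deg[[1]], c(0.5, 0.5))
  expect_equal(off_deg[[2]], c(0.5, 0.5))
})

test_that("mutation perturbs one coordinate and conserves the simplex", {
  cfg <- ga_config(mutation_rate = 1, mutation_scale = 0.05)
  # deterministic check of the complementary K=2 update
  set.seed(31)
  w <- c(0.5, 0.5)
  m <- ga_mutate(w, cfg)
  expect_lt(abs(sum(m) - 1), 1e-9)
  expect_true(all(m >= 0 & m <= 1))
  expect_lt(max(abs(m - w)), 0.05 + 1e-12)
  # clipping at the vertex: (1, 0) stays put when delta pushes above 1
  set.seed(1)  # first runif draws land delta on coordinate 1 positive or clip
  for (i in 1:50) {
    m2 <- ga_mutate(c(1, 0), cfg)
    expect_lt(abs(sum(m2) - 1), 1e-9)
    expect_true(all(m2 >= 0 & m2 <= 1))
  }
})

test_that("simplex invariant survives 10^4 fuzzed init/crossover/mutate ops", {
  cfg <- ga_config(mutation_rate = 1)
  set.seed(41)
  worst <- 0
  for (i in 1:2500) {
    k <- sample(2:5, 1)
    g <- rgamma(k, 1); w1 <- g / sum(g)
    g <- rgamma(k, 1); w2 <- g / sum(g)
    off <- ga_crossover(w1, w2)          # 2 ops
    m1 <- ga_mutate(off[[1]], cfg)       # 1 op
    m2 <- ga_mutate(off[[2]], cfg)       # 1 op
    for (w in list(off[[1]], off[[2]], m1, m2)) {
      worst <- max(worst, abs(sum(w) - 1), -min(w, 0), max(w) - 1)
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("the optimizer is reproducible and its elitist trace is monotone", {
  b <- simulate_bundle(scenario_s1(seed = 7))
  cfg <- ga_config(max_generations = 15)
  f1 <- ga_fuse(b, cfg, seed = 7)
  f2 <- ga_fuse(b, cfg, seed = 7)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$trace, f2$trace)
  expect_true(all(diff(f1$trace$best_fitness) >= 0))
  expect_equal(f1$fitness, max(f1$trace$best_fitness))
  expect_equal(f1$termination, "max_generations")
  # fitness_target stops early
  f3 <- ga_fuse(b, ga_config(fitness_target = 0.5), seed = 7)
  expect_equal(f3$termination, "fitness_target")
  expect_lte(f3$generations, 1)
})

test_that("a flat fitness landscape returns the shared accuracy", {
  b <- simulate_bundle(scenario_config(n_samples = 150, n_classes = 4,
                                       model_accuracies = c(0.7, 0.7),
                                       sharpness = 1e4, seed = 2))
  bi <- model_bundle(list(m1 = b$matrices[[1]], m2 = b$matrices[[1]]),
                     labels = b$labels)
  acc <- mean(predict_classes(bi$matrices[[1]]) == bi$labels)
  fit <- ga_fuse(bi, ga_config(max_generations = 5), seed = 4)
  expect_equal(fit$fitness, acc)
})

test_that("model-object methods expose weights, predictions and the trace", {
  b <- simulate_bundle(scenario_s1(seed = 3))
  fit <- ga_fuse(b, ga_config(max_generations = 8), seed = 3)
  w <- coef(fit)
  expect_named(w, c("model_1", "model_2"))
  expect_lt(abs(sum(w) - 1), 1e-9)
  pr <- predict(fit, type = "prob")
  expect_s3_class(pr, "probability_matrix")
  expect_identical(predict(fit), predict_classes(pr))
  expect_equal(unclass(fitted(fit)), unclass(pr))
  expect_output(print(fit), "ensemble accuracy")
  expect_output(summary(fit), "standalone")
  tf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tf); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tf))
})

test_that("grid search enumerates the simplex grid with lexicographic ties", {
  b <- tiny_bundle(pm(c(1, 0), c(0, 1)), pm(c(0, 1), c(1, 0)),
                   labels = c(0L, 1L))
  g <- grid_search_weights(b, step = 0.5)
  expect_equal(sort(g$grid$w1), c(0, 0.5, 1))
  # identical models: every grid point ties; lexicographically smallest wins
  bi <- tiny_bundle(pm(c(0.9, 0.1), c(0.2, 0.8)), pm(c(0.9, 0.1), c(0.2, 0.8)),
                    labels = c(0L, 1L))
  gi <- grid_search_weights(bi, step = 0.25)
  expect_equal(gi$weights, c(0, 1))
  expect_error(grid_search_weights(b, step = 0.6), "step")
  # K = 3 grid covers the simplex
  b3 <- model_bundle(list(pm(c(1, 0)), pm(c(0, 1)), pm(c(0.5, 0.5))),
                     labels = 0L)
  g3 <- grid_search_weights(b3, step = 0.5)
  expect_true(all(abs(rowSums(g3$grid[, 1:3]) - 1) < 1e-9))
  expect_equal(nrow(g3$grid), 6)  # (0,0,1),(0,.5,.5),(0,1,0),(.5,0,.5),(.5,.5,0),(1,0,0)
})

test_that("exact breakpoint oracle dominates any finite grid", {
  for (s in 1:5) {
    b <- simulate_bundle(scenario_s1(seed = 400 + s))
    ex <- exact_max_accuracy(b)
    g_coarse <- grid_search_weights(b, step = 0.01)
    expect_gte(ex$max_accuracy, g_coarse$fitness)
    expect_equal(ex$max_accuracy,
                 ga_fitness(ex$weight, b))
  }
  expect_error(exact_max_accuracy(model_bundle(
    list(pm(c(1, 0)), pm(c(0, 1)), pm(c(0.5, 0.5))), labels = 0L)), "K = 2")
})

test_that("a perfect model dominates a chance model through fusion", {
  cfg <- scenario_config(n_samples = 300, n_classes = 5,
                         model_accuracies = c(1, 0.2), sharpness = 1e4,
                         error_correlation = 0)
  b <- simulate_bundle(cfg, seed = 11)
  expect_equal(mean(predict_classes(b$matrices[[1]]) == b$labels), 1)
  g <- grid_search_weights(b, step = 0.01)
  expect_equal(g$fitness, 1)
  fit <- ga_fuse(b, ga_config(), seed = 11)
  expect_equal(fit$fitness, 1)
})
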